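mkRecording <- function(dat, sfreq = 500, events = NULL, lost = NULL) {
  new("Recording", data = dat,
      channels = EEG_CHANNELS[seq_len(nrow(dat))], sfreq = sfreq,
      events = events %||% data.frame(onset = numeric(), label = character()),
      lostMask = lost %||% rep(FALSE, ncol(dat)),
      blinkPeriod = numeric(),
      injectionLog = data.frame(kind = character(), start = numeric(),
                                end = numeric(), channel = character()),
      meta = list())
}

test_that("common-average reference removes a shared offset exactly", {
  set.seed(1)
  dat <- matrix(stats::rnorm(7 * 1000), 7)
  recA <- preprocess(mkRecording(dat), "validation")
  recB <- preprocess(mkRecording(dat + 10), "validation")
  expect_equal(recA@data, recB@data, tolerance = 1e-6)
})

test_that("the band-pass attenuates 50 Hz per the analytic response and keeps 10 Hz", {
  t <- seq(0, 10, by = 1 / 500)
  mid <- 1000:4000
  s50 <- matrix(rep(sin(2 * pi * 50 * t), 2), 2, byrow = TRUE)
  f50 <- preprocess(mkRecording(s50), "bci")  # no CAR: pure filter response
  att <- 20 * log10(stats::sd(f50@data[1, mid]) / stats::sd(s50[1, mid]))
  closedForm <- -2 * 10 * log10(1 + (50 / 30)^8)  # order 4, two passes
  expect_lt(att, -30)
  expect_lt(abs(att - closedForm), 5)
  s10 <- matrix(rep(sin(2 * pi * 10 * t), 2), 2, byrow = TRUE)
  f10 <- preprocess(mkRecording(s10), "bci")
  expect_lt(abs(stats::sd(f10@data[1, mid]) / stats::sd(s10[1, mid]) - 1),
            0.05)
  expect_error(preprocess(mkRecording(s10), band = c(1, 400)), "Nyquist")
})

test_that("blink projection removes blink variance but preserves Oz alpha", {
  pr <- taskProtocol("eyes", seed = 2, blinkPeriodS = 20)
  rec0 <- synthTaskRecording(pr, effectSpec(), deviceProfile("egi_like"),
                             seed = 5)
  rec <- injectArtifacts(rec0, effectSpec(nLostRuns = 0L, nAmpArtifacts = 0L,
                                          nDriftSegments = 0L), seed = 6)
  clean <- blinkProject(rec)
  bw <- clean@meta$blinkWindows
  expect_gt(nrow(bw), 5)
  idx <- unlist(apply(as.matrix(bw) * 500, 1,
                      function(w) max(1, round(w[1])):round(w[2]),
                      simplify = FALSE))
  fpz <- match("Fpz", channelNames(rec))
  expect_gt(1 - stats::var(clean@data[fpz, idx]) /
              stats::var(rec@data[fpz, idx]), 0.8)
  oz <- match("Oz", channelNames(rec))
  span <- 20000:40000
  p0 <- welchPsd(rec0@data[oz, span], 500)
  p1 <- welchPsd(clean@data[oz, span], 500)
  k <- p0$freq >= 8 & p0$freq <= 12
  expect_lt(abs(sum(p1$psd[k]) / sum(p0$psd[k]) - 1), 0.10)
  # blink-free recording passes through unchanged, with a warning
  set.seed(9)
  quiet <- mkRecording(matrix(stats::rnorm(7 * 5000, sd = 5), 7))
  expect_warning(same <- blinkProject(quiet), "no blinks")
  expect_identical(same@data, quiet@data)
})

test_that("task windows produce the documented epoch geometry", {
  pr <- taskProtocol("eyes", seed = 1, blinkPeriodS = 5)
  rec <- synthTaskRecording(pr, effectSpec(), deviceProfile("egi_like"),
                            seed = 1)
  ep <- extractEpochs(rec, "eyes")
  expect_identical(nTrials(ep), 20L)
  expect_equal(diff(range(epochTimes(ep))), 4.5 - 1 / 500)
  ps <- taskProtocol("ssvep", seed = 1, blinkPeriodS = 5)
  recS <- synthTaskRecording(ps, effectSpec(), deviceProfile("egi_like"),
                             seed = 1)
  epS <- extractEpochs(recS, "ssvep")
  expect_identical(sum(trialLabels(epS) == "ssvep_5"), 9L)  # 3 per 10 s trial
  expect_equal(dim(epochData(epS))[3], 2500)                # 5 s at 500 Hz
  # flat signal: oddball baseline correction zeroes the epoch exactly
  n <- 5000
  ev <- data.frame(onset = c(4, 6), label = c("target", "nontarget"))
  recO <- mkRecording(matrix(5, 7, n), events = ev)
  recO@meta$task <- "oddball"
  epO <- extractEpochs(recO, "oddball")
  expect_true(all(abs(epochData(epO)) < 1e-12))
  expect_equal(range(epochTimes(epO)), c(-0.2, 0.7 - 1 / 500))
  epB <- extractEpochs(recO, "oddball", mode = "bci")
  expect_equal(range(epochTimes(epB)), c(0, 0.7 - 1 / 500))
  # marker outside the recording is skipped with a warning
  ev2 <- data.frame(onset = c(4, 9.9), label = c("target", "target"))
  recO2 <- mkRecording(matrix(5, 7, n), events = ev2)
  expect_warning(ep2 <- extractEpochs(recO2, "oddball"), "skipped")
  expect_identical(nTrials(ep2), 1L)
})

test_that("rejection rules honour their boundary semantics exactly", {
  set.seed(4)
  n <- 2250
  mk <- function(x, lost = rep(FALSE, n))
    makeEpochs(array(rep(x, each = 1), c(1, 1, n)), 500,
               lostMask = matrix(lost, 1, n))
  # loss: strictly more than 20 consecutive samples
  noise <- stats::rnorm(n)
  l20 <- rep(FALSE, n); l20[101:120] <- TRUE
  l21 <- rep(FALSE, n); l21[101:121] <- TRUE
  expect_false(rejected(rejectEpochs(mk(noise, l20)))[1])
  ep21 <- rejectEpochs(mk(noise, l21))
  expect_identical(rejectReason(ep21)[1], "loss")
  # amplitude: 60 uV sinusoid rejected, 40 uV kept
  t <- seq_len(n) / 500
  expect_identical(rejectReason(rejectEpochs(mk(60 * sin(2 * pi * 7 * t))))[1],
                   "amplitude")
  expect_false(rejected(rejectEpochs(mk(40 * sin(2 * pi * 7 * t))))[1])
  # linear: perfect ramp rejected, white noise kept
  ramp <- seq(-40, 40, length.out = n)
  expect_identical(rejectReason(rejectEpochs(mk(ramp)))[1], "linear")
  expect_false(rejected(rejectEpochs(mk(5 * noise)))[1])
  # r^2 threshold is strict: just-below mix kept, just-above rejected
  mix <- function(a) a * scale(seq_len(n))[, 1] + sqrt(1 - a^2) *
    scale(stats::rnorm(n))[, 1]
  r2of <- function(x) stats::cor(x, seq_len(n))^2
  lo <- mix(sqrt(0.80)); hi <- mix(sqrt(0.90))
  expect_lt(r2of(lo), 0.85); expect_gt(r2of(hi), 0.85)
  expect_false(rejected(rejectEpochs(mk(lo)))[1])
  expect_identical(rejectReason(rejectEpochs(mk(hi)))[1], "linear")
  # constant channel defines r^2 = 0 and survives
  expect_false(rejected(rejectEpochs(mk(rep(0, n))))[1])
  # psd rule: mean dB in 20-30 Hz above 60 (amplitude bound widened so the
  # psd rule can be reached; see the rule-order note in the vignette)
  burst <- 6000 * sin(2 * pi * 25 * t)
  epP <- rejectEpochs(mk(burst), ampLimitUv = Inf)
  expect_identical(rejectReason(epP)[1], "psd")
  expect_false(rejected(rejectEpochs(mk(30 * sin(2 * pi * 25 * t)),
                                     ampLimitUv = Inf))[1])
  # bci mode: 100 uV bound, loss + amplitude only
  expect_false(rejected(rejectEpochs(mk(60 * sin(2 * pi * 7 * t)), "bci"))[1])
  expect_identical(rejectReason(rejectEpochs(mk(120 * sin(2 * pi * 7 * t)),
                                             "bci"))[1], "amplitude")
  expect_false(rejected(rejectEpochs(mk(ramp), "bci"))[1])  # no linear rule
})

test_that("every injected artifact is caught by its intended rule", {
  pr <- taskProtocol("eyes", seed = 2, blinkPeriodS = 10)
  rec0 <- synthTaskRecording(pr, effectSpec(), deviceProfile("biohub_like"),
                             seed = 7)
  ev <- recordingEvents(rec0)
  rec <- injectArtifacts(rec0, effectSpec(blinkRateHz = 0), seed = 8,
                         blinkTimes = numeric(),
                         lossAt = ev$onset[2] + 2, ampAt = ev$onset[5] + 2,
                         driftAt = ev$onset[9] + 0.3)
  # loss and amplitude through the faithful pipeline (filtered)
  epF <- rejectEpochs(extractEpochs(preprocess(rec), "eyes"))
  expect_identical(rejectReason(epF)[2], "loss")
  expect_identical(rejectReason(epF)[5], "amplitude")
  # saturation-like drift via raw epochs (a 1 Hz high-pass removes ramps;
  # the linear rule targets unfiltered drift segments)
  epR <- rejectEpochs(extractEpochs(rec, "eyes"))
  expect_identical(rejectReason(epR)[9], "linear")
  # clean epochs survive: false-rejection rate < 5% at default noise
  bad <- 0L; tot <- 0L
  for (s in 1:5) {
    r <- preprocess(synthTaskRecording(pr, effectSpec(),
                                       deviceProfile("biohub_like"),
                                       seed = s))
    e <- rejectEpochs(extractEpochs(r, "eyes"))
    bad <- bad + sum(rejected(e)); tot <- tot + nTrials(e)
  }
  expect_lt(bad / tot, 0.05)
  report <- rejectionReport(epF)
  expect_true(all(c(2L, 5L) %in% report$trial))
})
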