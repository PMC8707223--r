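test_that("oddball sequences honour the pairing rule and never repeat targets", {
  lab <- genOddballSequence(10, seed = 1)
  expect_identical(sum(lab == "target"), 10L)
  expect_identical(sum(lab == "nontarget"), 60L)
  expect_identical(sum(genOddballSequence(1, seed = 2) == "nontarget"), 6L)
  for (s in 1:20) {
    lab <- genOddballSequence(12, seed = s)
    expect_identical(sum(lab == "target"), 12L)
    expect_identical(length(lab), 84L)
    expect_false(any(lab[-1] == "target" & lab[-length(lab)] == "target"))
  }
  # label multiset identical across seeds, only order varies
  expect_identical(sort(genOddballSequence(11, seed = 5)),
                   sort(genOddballSequence(11, seed = 6)))
  expect_warning(genOddballSequence(3, ratio = 1 / 5.5), "rounding")
})

test_that("BCI carousel runs contain 18 trials with 3 targets", {
  for (s in 1:5) {
    run <- bciRunSequence(seed = s)
    expect_identical(nrow(run), 18L)
    expect_identical(sum(run$label == "target"), 3L)
    expect_identical(as.vector(table(run$icon)), rep(3L, 6))
  }
})

test_that("task protocols match the validation designs exactly", {
  pe <- taskProtocol("eyes", seed = 1)
  expect_identical(sum(pe$events$label == "open"), 10L)
  expect_identical(sum(pe$events$label == "closed"), 10L)
  expect_true(all(pe$events$duration == 5))
  pm <- taskProtocol("motor", seed = 1)
  expect_identical(sum(pm$events$label == "move"), 25L)
  rests <- pm$events$duration[pm$events$label == "rest"]
  expect_true(all(rests >= 8 & rests <= 12))
  ps <- taskProtocol("ssvep", seed = 1)
  expect_identical(sum(ps$events$label == "ssvep_5"), 3L)
  expect_identical(sum(ps$events$label == "ssvep_6"), 3L)
  expect_true(all(ps$events$duration[startsWith(ps$events$label, "ssvep")] == 10))
  po <- taskProtocol("oddball", seed = 1)
  nT <- sum(po$events$label == "target")
  runsGap <- diff(po$events$onset)
  expect_identical(sum(runsGap > 1), 4L)  # 5 runs
  expect_true(nT >= 50 && nT <= 60)       # 5 runs x 10-12 targets
  expect_identical(sum(po$events$label == "nontarget"), 6L * nT)
  withinRun <- runsGap[runsGap < 1]
  expect_true(all(abs(withinRun - 0.6) < 1e-9))  # 200 ms stim + 400 ms ISI
})

test_that("features appear at the physiologically correct channels", {
  eff <- effectSpec()
  pr <- taskProtocol("eyes", seed = 3, blinkPeriodS = 5)
  for (s in 1:3) {
    rec <- synthTaskRecording(pr, eff, deviceProfile("egi_like"), seed = s)
    ep <- extractEpochs(preprocess(rec), "eyes")
    oz <- match("Oz", channelNames(ep))
    bandPower <- function(tr) {
      ps <- welchPsd(epochData(ep)[tr, oz, ], 500)
      sum(ps$psd[ps$freq >= 8 & ps$freq <= 12])
    }
    pClosed <- mean(vapply(which(trialLabels(ep) == "closed"), bandPower,
                           numeric(1)))
    pOpen <- mean(vapply(which(trialLabels(ep) == "open"), bandPower,
                         numeric(1)))
    expect_gt(pClosed, pOpen)
  }
  # P300 at Cz, inside the canonical latency window
  po <- taskProtocol("oddball", seed = 4, blinkPeriodS = 5)
  rec <- preprocess(synthTaskRecording(po, eff, deviceProfile("egi_like"),
                                       seed = 11))
  ep <- extractEpochs(rec, "oddball")
  av <- erpAverage(ep, "Cz", peakWindow = c(0.25, 0.55))
  cz <- match("Cz", channelNames(ep))
  dif <- av$target$mean[cz, ] - av$nontarget$mean[cz, ]
  tPeak <- epochTimes(ep)[which.max(dif)]
  expect_true(tPeak >= 0.25 && tPeak <= 0.40)
})

test_that("the noisy device profile has strictly higher broadband power", {
  pr <- taskProtocol("eyes", seed = 2, blinkPeriodS = 5)
  for (s in 1:3) {
    a <- synthTaskRecording(pr, effectSpec(), deviceProfile("egi_like"),
                            seed = s)
    b <- synthTaskRecording(pr, effectSpec(), deviceProfile("biohub_like"),
                            seed = s)
    fz <- match("Fz", channelNames(a))  # feature-free channel
    expect_gt(stats::var(b@data[fz, ]), stats::var(a@data[fz, ]))
  }
})

test_that("artifact injection logs ground truth and honours explicit sites", {
  pr <- taskProtocol("eyes", seed = 2, blinkPeriodS = 5)
  rec <- synthTaskRecording(pr, effectSpec(), deviceProfile("biohub_like"),
                            seed = 3)
  eff <- effectSpec()
  out <- injectArtifacts(rec, eff, seed = 4, blinkTimes = c(1, 2.5),
                         lossAt = 10, ampAt = 20, driftAt = 30)
  log <- injectionLog(out)
  expect_identical(sort(unique(log$kind)),
                   c("amplitude", "blink", "drift", "loss"))
  expect_identical(sum(out@lostMask), as.integer(eff@lostRunLength))
  # blink is largest at Fpz
  idx <- round(1 * 500):round(1.3 * 500)
  dif <- abs(out@data[, idx] - rec@data[, idx])
  expect_identical(unname(which.max(rowMeans(dif))),
                   match("Fpz", channelNames(rec)))
  # blinkRate 0 and no explicit sites leaves the signal unchanged
  quiet <- injectArtifacts(rec, effectSpec(blinkRateHz = 0, nLostRuns = 0L,
                                           nAmpArtifacts = 0L,
                                           nDriftSegments = 0L), seed = 5)
  expect_identical(quiet@data, rec@data)
})
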