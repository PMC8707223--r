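test_that("magnitude trace matches a brute-force per-sample norm", {
  s <- streams(tinySession(seed = 1))[[1]]
  s@samples <- matrix(c(3, 4, 0), 3, 10)
  s@lostMask <- rep(FALSE, 10)
  s@rawTimestamps <- seq(0, by = 0.001, length.out = 10)
  expect_equal(magnitudeTrace(s), rep(0, 10))  # constant 5, mean-removed
  set.seed(2)
  s@samples <- matrix(stats::rnorm(30), 3, 10)
  bf <- sqrt(colSums(s@samples^2))
  expect_equal(magnitudeTrace(s), bf - mean(bf))
  s@samples <- matrix(c(-2, 1, 3, -1), 1, 4)
  s@rawTimestamps <- s@rawTimestamps[1:4]
  s@lostMask <- rep(FALSE, 4)
  expect_equal(magnitudeTrace(s), abs(c(-2, 1, 3, -1)) - mean(abs(c(-2, 1, 3, -1))))
  s@samples <- matrix(0, 2, 4)
  expect_error(magnitudeTrace(s), "1- or 3-axis")
})

test_that("resampling onto the common grid preserves an analytic sine", {
  n <- 3000
  t5 <- seq(0, by = 1 / 500, length.out = n)
  s <- new("SimStream", device = deviceSpec("d", 500),
           samples = matrix(2 + sin(2 * pi * 5 * t5), 1, n),
           rawTimestamps = t5, sharedTimestamps = t5,
           lostMask = rep(FALSE, n),
           offsetHistory = cbind(c(0, 1), c(0, 0)), meta = list())
  ref <- new("SimStream", device = deviceSpec("r", 1000),
             samples = matrix(0, 1, 2 * n),
             rawTimestamps = seq(0, by = 1e-3, length.out = 2 * n),
             sharedTimestamps = seq(0, by = 1e-3, length.out = 2 * n),
             lostMask = rep(FALSE, 2 * n),
             offsetHistory = cbind(c(0, 1), c(0, 0)), meta = list())
  sess <- new("SimSession", streams = list(ref, s), groundTruth = list(),
              duration = 6, seed = 1L)
  rs <- resampleCommon(sess)
  tg <- rs$times
  want <- (2 + sin(2 * pi * 5 * tg)) - mean(2 + sin(2 * pi * 5 * tg))
  expect_lt(max(abs(rs$traces$d - want)), 0.01)
  expect_equal(length(tg), 1000 * (max(t5) - 0), tolerance = 2e-3)
})

test_that("no temporal overlap raises a calibration error", {
  sess <- tinySession(seed = 2)
  sess <- synchronizeSession(sess)
  sess@streams[[2]]@sharedTimestamps <-
    sess@streams[[2]]@sharedTimestamps + 100
  expect_error(resampleCommon(sess), "overlap")
})

test_that("perturbation chunks are found where designed and not in noise", {
  set.seed(3)
  falsePos <- 0L
  for (r in 1:100) {
    if (nrow(findPerturbationChunks(stats::rnorm(20000), 1000,
                                    errorOnEmpty = FALSE)) > 0)
      falsePos <- falsePos + 1L
  }
  expect_lt(falsePos / 100, 0.01 + 1e-9)
  # one stroke at t = 5 s -> exactly one window containing it
  prof <- perturbationProfile(strokeTimes = 5)
  m <- simulateMotion(prof, 10, 1000, 4)
  tr <- sqrt(colSums(m^2))
  ch <- findPerturbationChunks(tr - mean(tr), 1000)
  expect_identical(nrow(ch), 1L)
  expect_true(ch$startIndex[1] <= 5001 && ch$endIndex[1] >= 5001)
  # continuous movement 7-9 s -> window covering >= 90% of it
  prof2 <- perturbationProfile(nStrokes = 0L, movementWindows = c(7, 9))
  m2 <- simulateMotion(prof2, 12, 1000, 5)
  tr2 <- sqrt(colSums(m2^2))
  ch2 <- findPerturbationChunks(tr2 - mean(tr2), 1000)
  cover <- sum(pmin(ch2$endIndex, 9000) - pmax(ch2$startIndex, 7001) + 1)
  expect_gt(cover / 2000, 0.9)
  expect_error(findPerturbationChunks(stats::rnorm(5000), 1000), "stronger")
})

test_that("cross-correlation lag matches a brute-force shift scan", {
  set.seed(8)
  base <- stats::rnorm(4000)
  base[1800:1900] <- base[1800:1900] + 20 * exp(-0.5 * ((0:100 - 50) / 15)^2)
  other <- c(rep(0, 40), base)[1:4000]
  chunks <- data.frame(startIndex = 1700, endIndex = 2000)
  est <- estimatePairwiseLag(base, base, chunks, maxLagMs = 200)
  expect_equal(est$lagMs, 0)
  est2 <- estimatePairwiseLag(base, other, chunks, maxLagMs = 200)
  expect_equal(est2$lagMs, 40)
  # independent oracle: direct correlation over every integer shift
  idx <- 1700:2000
  cc <- vapply(-200:200, function(L)
    stats::cor(base[idx], other[idx + L]), numeric(1))
  expect_equal(est2$lagMs, (-200:200)[which.max(cc)])
})

test_that("chunks near the trace edge are skipped, all skipped errors", {
  x <- stats::rnorm(1000)
  expect_warning(
    expect_error(
      estimatePairwiseLag(x, x, data.frame(startIndex = 10, endIndex = 300),
                          maxLagMs = 500),
      "every chunk"),
    "skipped")
})

test_that("offset matrix statistics and sample conversion are exact", {
  nms <- c("jetson", "openbci")
  lagm <- function(v) matrix(c(0, -v, v, 0), 2, dimnames = list(nms, nms))
  rates <- c(jetson = 1000, openbci = 500)
  mat <- buildOffsetMatrix(list(lagm(38), lagm(40), lagm(42)), rates)
  expect_equal(meanMs(mat)["jetson", "openbci"], 40)
  expect_equal(sdMs(mat)["jetson", "openbci"], 2)  # sample sd of {38,40,42}
  expect_identical(offsetSamples(mat)["jetson", "openbci"], 20L)
  expect_warning(one <- buildOffsetMatrix(list(lagm(40)), rates), "single")
  expect_equal(sdMs(one)["jetson", "openbci"], 0)
})

test_that("a simulated 40 ms wireless latency is recovered within 2 ms", {
  sess <- synchronizeSession(tinySession(seed = 21, lat = c(0, 0.040)))
  lag <- sessionLagMatrix(sess)
  expect_lt(abs(lag["ref", "dev"] - 40), 2)
  # antisymmetry before antisymmetrization
  expect_lt(abs(lag["ref", "dev"] + lag["dev", "ref"]), 2)
})

test_that("compensation closes the loop: residual lags at or below 1 ms", {
  sess <- synchronizeSession(tinySession(seed = 22, lat = c(0, 0.040)))
  mat <- suppressWarnings(
    buildOffsetMatrix(list(sessionLagMatrix(sess)),
                      c(ref = 1000, dev = 500)))
  comp <- compensateStreams(sess, mat, "ref")
  resid <- sessionLagMatrix(comp)
  expect_lte(max(abs(resid)), 1)
  # reference stream untouched
  expect_equal(streams(comp)[[1]]@sharedTimestamps,
               streams(sess)[[1]]@sharedTimestamps)
  # compensating twice shifts by exactly twice the offset
  comp2 <- compensateStreams(comp, mat, "ref")
  shift1 <- streams(sess)[[2]]@sharedTimestamps -
    streams(comp)[[2]]@sharedTimestamps
  shift2 <- streams(sess)[[2]]@sharedTimestamps -
    streams(comp2)[[2]]@sharedTimestamps
  expect_equal(shift2, 2 * shift1)
  expect_error(compensateStreams(sess, mat, "nope"), "missing")
})

test_that("a 25 Hz stream recovers within half its sampling interval", {
  devs <- list(deviceSpec("ref", 1000), deviceSpec("imu", 25))
  clks <- list(clockModel(0, 0, 1e-3, 0, 0),
               clockModel(0.001, 10, 1e-3, 0.033, 0))
  prof <- perturbationProfile(nStrokes = 0L, movementWindows = c(4, 9),
                              movementBandwidth = 5, movementAmplitude = 5)
  sess <- synchronizeSession(simulateSession(devs, clks, prof, 12, seed = 31))
  lag <- sessionLagMatrix(sess)
  expect_lt(abs(lag["ref", "imu"] - 33), 1000 / 25 / 2)
})

test_that("the offset report mirrors the bench table layout", {
  nms <- c("jetson", "openbci")
  lagm <- matrix(c(0, -40, 40, 0), 2, dimnames = list(nms, nms))
  mat <- suppressWarnings(
    buildOffsetMatrix(list(lagm), c(jetson = 1000, openbci = 500)))
  path <- withr::local_tempfile(fileext = ".csv")
  writeOffsetReport(mat, path)
  rep <- utils::read.csv(path, check.names = FALSE)
  expect_identical(rep$device, nms)
  expect_match(rep$openbci[1], "40 \\+/- 0 \\[20\\]")
  expect_identical(rep$jetson[2], "")
})
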