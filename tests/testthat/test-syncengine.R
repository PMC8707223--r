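test_that("constant offset history fits intercept with zero slope", {
  fit <- fitClockCorrection(cbind(c(0, 10), c(0.005, 0.005)))
  expect_equal(fit@intercept, 0.005)
  expect_equal(fit@slope, 0)
})

test_that("noise-free drifting clock is recovered in closed form", {
  t <- seq(0, 300, by = 5)
  h <- cbind(t, 0.002 + 5e-5 * t)
  fit <- fitClockCorrection(h)
  expect_equal(fit@slope, 5e-5, tolerance = 1e-9)
  expect_equal(fit@intercept, 0.002, tolerance = 1e-12)
})

test_that("a gross outlier barely moves the fitted slope", {
  t <- seq(0, 95, by = 5)
  o <- 0.003 + 2e-5 * t + stats::rnorm(length(t), sd = 1e-4)
  clean <- fitClockCorrection(cbind(t, o))
  o2 <- o
  o2[10] <- o2[10] + 1  # +1 s handshake transient
  dirty <- fitClockCorrection(cbind(t, o2))
  expect_lt(abs(dirty@slope - clean@slope), 0.1 * abs(clean@slope) + 1e-7)
  expect_lt(abs(dirty@intercept - clean@intercept), 5e-4)
})

test_that("fewer than two measurements is unsynchronizable", {
  expect_error(fitClockCorrection(cbind(0, 0.005)), "unsynchronizable")
})

test_that("clock parameter recovery holds over 200 seeded repetitions", {
  set.seed(42)
  ok <- 0L
  for (r in 1:200) {
    off <- stats::runif(1, -0.1, 0.1)
    drift <- stats::runif(1, -1e-4, 1e-4)
    t <- seq(0, 600, by = 5)
    h <- cbind(t, off + drift * t + stats::rnorm(length(t), sd = 5e-4))
    fit <- fitClockCorrection(h)
    if (abs(fit@intercept - off) < 5e-4 && abs(fit@slope - drift) < 5e-6)
      ok <- ok + 1L
  }
  expect_gte(ok, 190)
})

test_that("remapping is an identity for an identity clock and inverts exactly", {
  sess <- tinySession(seed = 7, jitterSd = 0, driftPpm = c(0, 0),
                      offset0 = c(0, 0), offsetNoiseSd = 0)
  s <- streams(sess)[[1]]
  r <- remapTimestamps(s, fitClockCorrection(s))
  expect_equal(r@sharedTimestamps, s@rawTimestamps, tolerance = 1e-12)
  sess2 <- tinySession(seed = 8)
  s2 <- remapTimestamps(streams(sess2)[[2]])
  inv <- remapTimestamps(s2, s2@meta$correction, invert = TRUE)
  expect_equal(inv@rawTimestamps, streams(sess2)[[2]]@rawTimestamps,
               tolerance = 1e-12)
})

test_that("remapping aligns two streams differing only by offset0", {
  prof <- perturbationProfile(strokeTimes = 3, baselineNoiseSd = 0)
  m <- simulateMotion(prof, 6, 1000, 2)
  dev <- deviceSpec("d", 1000)
  jit <- 2e-4
  sA <- sampleStream(m, dev, clockModel(0, 0, jit), seed = 1,
                     offsetNoiseSd = 0)
  sB <- sampleStream(m, dev, clockModel(0.050, 0, jit), seed = 2,
                     offsetNoiseSd = 0)
  sA <- remapTimestamps(sA)
  sB <- remapTimestamps(sB)
  pkA <- sA@sharedTimestamps[which.max(sqrt(colSums(sA@samples^2)))]
  pkB <- sB@sharedTimestamps[which.max(sqrt(colSums(sB@samples^2)))]
  expect_lt(abs(pkA - pkB), 2 * jit + 1 / 1000)
})

test_that("remapping bounds the event-time discrepancy of drifting clocks", {
  # 10-minute session, two drifting clocks: discrepancy without correction
  # grows to ~60 ms; after remapping it stays below 2 ms.
  t <- seq(0, 600, by = 5)
  mkStream <- function(off, drift) {
    h <- cbind(t, off + drift * t + stats::rnorm(length(t), sd = 2e-4))
    fitClockCorrection(h)
  }
  set.seed(11)
  fA <- mkStream(0.010, 1e-4)
  fB <- mkStream(-0.020, -5e-5)
  ev <- 590  # reference event near the session end
  rawA <- ev * (1 + 1e-4) + 0.010
  rawB <- ev * (1 - 5e-5) - 0.020
  expect_gt(abs(rawA - rawB), 0.05)
  shA <- rawA - correctedOffset(fA, rawA)
  shB <- rawB - correctedOffset(fB, rawB)
  expect_lt(abs(shA - shB), 2e-3)
})

test_that("dejittering leaves noise-free grids untouched and restores jittered ones", {
  sess0 <- tinySession(seed = 1, jitterSd = 0, driftPpm = c(0, 0),
                       offset0 = c(0, 0), offsetNoiseSd = 0)
  s0 <- dejitter(remapTimestamps(streams(sess0)[[1]]))
  expect_equal(s0@sharedTimestamps, streams(sess0)[[1]]@rawTimestamps,
               tolerance = 1e-12)
  prof <- perturbationProfile(nStrokes = 0L, baselineNoiseSd = 0.01)
  m <- simulateMotion(prof, 60, 1000, 1)
  st <- sampleStream(m, deviceSpec("d", 500), clockModel(jitterSd = 1e-3),
                     seed = 3, offsetNoiseSd = 0)
  st <- dejitter(remapTimestamps(st))
  grid <- seq(0, by = 1 / 500, length.out = length(st@sharedTimestamps))
  expect_lt(sqrt(mean((st@sharedTimestamps - grid)^2)), 1e-4)
  # exactly equispaced within the (single) segment
  expect_lt(diff(range(diff(st@sharedTimestamps))), 1e-12)
})

test_that("a 100 ms dropout splits the stream into exactly two segments", {
  s <- new("SimStream", device = deviceSpec("d", 500),
           samples = matrix(0, 3, 200),
           rawTimestamps = c(seq(0, by = 0.002, length.out = 100),
                             seq(0.298, by = 0.002, length.out = 100)),
           sharedTimestamps = numeric(), lostMask = rep(FALSE, 200),
           offsetHistory = cbind(c(0, 1), c(0, 0)), meta = list())
  s <- dejitter(remapTimestamps(s, fitClockCorrection(s)))
  expect_identical(nrow(s@meta$segments), 2L)
})

test_that("lost-run detection agrees with a brute-force scan", {
  expect_identical(nrow(detectLostRuns(rep(FALSE, 50))), 0L)
  mask <- rep(FALSE, 100)
  mask[40:60] <- TRUE
  runs <- detectLostRuns(mask)
  expect_equal(runs$start, 40)
  expect_equal(runs$length, 21)
  set.seed(6)
  for (r in 1:20) {
    mask <- stats::runif(200) < 0.2
    runs <- detectLostRuns(mask)
    # brute-force oracle
    oracle <- list()
    i <- 1
    while (i <= length(mask)) {
      if (mask[i]) {
        j <- i
        while (j < length(mask) && mask[j + 1]) j <- j + 1
        oracle[[length(oracle) + 1]] <- c(i, j - i + 1)
        i <- j + 1
      } else i <- i + 1
    }
    om <- do.call(rbind, oracle)
    if (is.null(om)) {
      expect_identical(nrow(runs), 0L)
    } else {
      expect_equal(runs$start, om[, 1])
      expect_equal(runs$length, om[, 2])
    }
  }
})
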