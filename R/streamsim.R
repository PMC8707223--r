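#' Create a clock model
#'
#' @param offset0 initial clock offset vs. the shared reference, seconds.
#' @param driftPpm clock-rate error in parts per million (50 -> 5e-5).
#' @param jitterSd per-sample timestamp noise sd, seconds.
#' @param transportLatency mean wireless content delay, seconds. Invisible to
#'   clock synchronization; redrawn at each session startup.
#' @param transportLatencySd across-startup sd of the transport latency, seconds.
#' @return a [ClockModel-class].
#' @examples
#' clockModel(offset0 = 2e-3, driftPpm = 50, transportLatency = 0.040)
#' @export
clockModel <- function(offset0 = 0, driftPpm = 0, jitterSd = 0,
                       transportLatency = 0, transportLatencySd = 0) {
  new("ClockModel", offset0 = offset0, drift = driftPpm * 1e-6,
      jitterSd = jitterSd, transportLatency = transportLatency,
      transportLatencySd = transportLatencySd)
}

#' Create a device specification
#'
#' @param name device identifier.
#' @param nominalRate sampling rate, Hz. The bench devices stream at 25, 500
#'   or 1000 Hz, but any positive rate is legal.
#' @param channelLabels channel names (default accelerometer xyz).
#' @param lossRate per-sample probability of starting a lost-sample run.
#' @param lossRunMean mean lost-run length in samples (geometric law).
#' @return a [DeviceSpec-class].
#' @export
deviceSpec <- function(name, nominalRate = 500,
                       channelLabels = c("x", "y", "z"),
                       lossRate = 0, lossRunMean = 5) {
  new("DeviceSpec", name = name, nominalRate = nominalRate,
      channelLabels = channelLabels, lossRate = lossRate,
      lossRunMean = lossRunMean)
}

#' Create a mechanical perturbation profile
#'
#' Describes the shared bench stimulus: impulsive strokes at the centre of the
#' rigid panel plus windows of band-limited random movement.
#'
#' @param nStrokes number of strokes (scheduled randomly unless
#'   \code{strokeTimes} is given).
#' @param strokeTimes optional explicit stroke centres, seconds.
#' @param strokeWidth stroke duration scale (Gaussian sigma is strokeWidth/2), s.
#' @param strokeAmplitude stroke peak amplitude, m/s^2; must exceed 5x the
#'   baseline noise sd so strokes are unambiguous calibration features.
#' @param movementWindows 2-column matrix (or vector of length 2) of movement
#'   (start, end) pairs, seconds.
#' @param movementBandwidth low-pass corner of the movement noise, Hz.
#' @param movementAmplitude RMS of the movement segments, m/s^2.
#' @param baselineNoiseSd baseline accelerometer noise sd, m/s^2.
#' @return a [PerturbationProfile-class].
#' @export
perturbationProfile <- function(nStrokes = 3L, strokeTimes = numeric(),
                                strokeWidth = 0.05, strokeAmplitude = 10,
                                movementWindows = matrix(numeric(), ncol = 2),
                                movementBandwidth = 8,
                                movementAmplitude = strokeAmplitude / 2,
                                baselineNoiseSd = 0.05) {
  if (is.vector(movementWindows) && length(movementWindows) == 2)
    movementWindows <- matrix(movementWindows, ncol = 2)
  new("PerturbationProfile", nStrokes = as.integer(nStrokes),
      strokeTimes = strokeTimes, strokeWidth = strokeWidth,
      strokeAmplitude = strokeAmplitude, movementWindows = movementWindows,
      movementBandwidth = movementBandwidth,
      movementAmplitude = movementAmplitude,
      baselineNoiseSd = baselineNoiseSd)
}

#' Simulate the ground-truth panel acceleration
#'
#' Generates the 3-axis acceleration of the rigid panel all devices are
#' mounted on: Gaussian baseline noise everywhere, band-limited random
#' movement inside the movement windows, and impulsive Gaussian strokes
#' (random 3-D direction) at the scheduled times. Deterministic given
#' \code{seed}.
#'
#' @param profile a [PerturbationProfile-class].
#' @param duration session duration, seconds.
#' @param rate sampling rate of the ground-truth trace, Hz (default 1000).
#' @param seed integer seed.
#' @return a 3 x n numeric matrix with attributes \code{rate} and
#'   \code{duration}; rows are the x, y, z axes.
#' @export
simulateMotion <- function(profile, duration, rate = 1000, seed = 1L) {
  stopIfNot(duration > 0, "duration must be positive")
  stopIfNot(rate >= 2 * profile@movementBandwidth,
            "rate must be at least twice the movement bandwidth")
  st <- profile@strokeTimes
  if (length(st) && (any(st < 0) || any(st > duration)))
    stop("stroke times must lie inside the session duration", call. = FALSE)
  mw <- profile@movementWindows
  if (nrow(mw) && (any(mw < 0) || any(mw > duration)))
    stop("movement windows must lie inside the session duration", call. = FALSE)

  n <- floor(duration * rate)
  t <- seq(0, by = 1 / rate, length.out = n)
  withSeed(seed, {
    acc <- matrix(stats::rnorm(3 * n, sd = profile@baselineNoiseSd), nrow = 3)
    # movement windows: low-passed white noise, edge-tapered, fixed RMS
    if (nrow(mw) && profile@movementAmplitude > 0) {
      bf <- signal::butter(4, min(profile@movementBandwidth / (rate / 2), 0.99),
                           type = "low")
      for (w in seq_len(nrow(mw))) {
        idx <- which(t >= mw[w, 1] & t < mw[w, 2])
        if (length(idx) < 8) next
        taperN <- min(round(0.1 * rate), floor(length(idx) / 4))
        taper <- rep(1, length(idx))
        if (taperN > 0) {
          ramp <- 0.5 - 0.5 * cos(pi * seq_len(taperN) / taperN)
          taper[seq_len(taperN)] <- ramp
          taper[length(idx) + 1 - seq_len(taperN)] <- ramp
        }
        for (ax in 1:3) {
          seg <- signal::filtfilt(bf, stats::rnorm(length(idx)))
          seg <- seg / max(stats::sd(seg), 1e-12) * profile@movementAmplitude
          acc[ax, idx] <- acc[ax, idx] + seg * taper
        }
      }
    }
    # strokes: Gaussian impulse along a random unit direction
    if (!length(st) && profile@nStrokes > 0) {
      # keep a margin at both ends so lag searches around a stroke never
      # run off the session
      lo <- max(2 * profile@strokeWidth, min(0.6, duration / 4))
      hi <- duration - lo
      st <- sort(stats::runif(profile@nStrokes, lo, max(hi, lo)))
    }
    sigma <- profile@strokeWidth / 2
    for (s0 in st) {
      dirv <- stats::rnorm(3)
      dirv <- dirv / sqrt(sum(dirv^2))
      idx <- which(abs(t - s0) <= 4 * sigma)
      pulse <- profile@strokeAmplitude * exp(-0.5 * ((t[idx] - s0) / sigma)^2)
      acc[, idx] <- acc[, idx] + outer(dirv, pulse)
    }
    attr(acc, "rate") <- rate
    attr(acc, "duration") <- duration
    attr(acc, "strokeTimes") <- st
    acc
  })
}

# Linear interpolation of a motion trace (channels x n with rate attr) at
# arbitrary times; constant extrapolation at the edges.
interpMotion <- function(motion, times) {
  rate <- attr(motion, "rate")
  tg <- seq(0, by = 1 / rate, length.out = ncol(motion))
  out <- matrix(0, nrow(motion), length(times))
  for (ch in seq_len(nrow(motion)))
    out[ch, ] <- stats::approx(tg, motion[ch, ], xout = times, rule = 2)$y
  out
}

#' Sample a ground-truth trace through a device and its clock
#'
#' Samples the shared motion at the device's nominal rate (linear
#' interpolation), delays the *content* by the transport latency, and builds
#' raw timestamps as \code{t_ref * (1 + drift) + offset0 + jitter}. Lost-run
#' starts are Bernoulli per sample with geometric run lengths; lost samples
#' are NA-valued and marked in the lost mask. A clock-offset measurement
#' history (the collector's periodic offset estimates) is generated at
#' \code{offsetInterval} with Gaussian measurement noise.
#'
#' @param motion matrix from [simulateMotion()].
#' @param device a [DeviceSpec-class].
#' @param clock a [ClockModel-class].
#' @param seed integer seed.
#' @param transportLatency optional latency override, seconds; defaults to the
#'   clock model's mean latency (no startup redraw). [simulateSession()]
#'   passes the per-startup draw here.
#' @param offsetInterval clock-offset measurement cadence, seconds.
#' @param offsetNoiseSd offset measurement noise sd, seconds (default 0.2 ms).
#' @return a [SimStream-class].
#' @export
sampleStream <- function(motion, device, clock, seed = 1L,
                         transportLatency = NULL,
                         offsetInterval = 5, offsetNoiseSd = 2e-4) {
  stopIfNot(device@nominalRate > 0, "nominalRate must be positive")
  duration <- attr(motion, "duration")
  lat <- if (is.null(transportLatency)) clock@transportLatency else transportLatency
  n <- floor(duration * device@nominalRate)
  tau <- seq(0, by = 1 / device@nominalRate, length.out = n)
  nch <- length(device@channelLabels)
  stopIfNot(nch <= nrow(motion),
            "device wants %d channels but motion has %d", nch, nrow(motion))
  withSeed(seed, {
    vals <- interpMotion(motion, tau - lat)[seq_len(nch), , drop = FALSE]
    raw <- tau * (1 + clock@drift) + clock@offset0
    if (clock@jitterSd > 0) {
      raw <- raw + stats::rnorm(n, sd = clock@jitterSd)
      raw <- enforceIncreasing(raw)
    }
    lost <- rep(FALSE, n)
    if (device@lossRate > 0) {
      starts <- which(stats::runif(n) < device@lossRate)
      lens <- stats::rgeom(length(starts), 1 / device@lossRunMean) + 1L
      for (k in seq_along(starts)) {
        i1 <- starts[k]
        i2 <- min(n, i1 + lens[k] - 1L)
        lost[i1:i2] <- TRUE
      }
    }
    vals[, lost] <- NA_real_
    mt <- seq(0, duration, by = offsetInterval)
    meas <- clock@offset0 + clock@drift * mt
    if (offsetNoiseSd > 0) meas <- meas + stats::rnorm(length(mt), sd = offsetNoiseSd)
    new("SimStream", device = device, samples = vals, rawTimestamps = raw,
        sharedTimestamps = numeric(), lostMask = lost,
        offsetHistory = cbind(time = mt, offset = meas),
        meta = list(transportLatency = lat, clock = clock))
  })
}

# Make a timestamp vector strictly increasing with minimal perturbation.
enforceIncreasing <- function(x) {
  n <- length(x)
  if (n < 2) return(x)
  for (i in 2:n) if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + 1e-9
  x
}

#' Simulate a complete multi-device session
#'
#' Draws a per-device transport latency for this startup (truncated normal),
#' samples every device's stream from one shared ground-truth motion, and
#' records the ground-truth pairwise content-offset matrix
#' \code{offsetMs[i, j] = (latency_j - latency_i) * 1000} (antisymmetric and
#' additive by construction; positive means device j trails device i).
#'
#' @param devices list of [DeviceSpec-class].
#' @param clocks list of [ClockModel-class], one per device.
#' @param profile a [PerturbationProfile-class].
#' @param duration session duration, seconds.
#' @param seed integer seed; all randomness (latency draws, motion, per-stream
#'   noise) derives from it.
#' @param offsetInterval,offsetNoiseSd see [sampleStream()].
#' @param motionRate ground-truth trace rate, Hz.
#' @return a [SimSession-class].
#' @export
simulateSession <- function(devices, clocks, profile, duration = 20,
                            seed = 1L, offsetInterval = 5,
                            offsetNoiseSd = 2e-4, motionRate = 1000) {
  stopIfNot(length(devices) == length(clocks),
            "need one clock model per device")
  seed <- as.integer(seed)
  nms <- vapply(devices, function(d) d@name, character(1))
  stopIfNot(!anyDuplicated(nms), "device names must be unique")
  lat <- withSeed(childSeed(seed, "startup"), {
    vapply(clocks, function(cl)
      max(0, stats::rnorm(1, cl@transportLatency, cl@transportLatencySd)),
      numeric(1))
  })
  motion <- simulateMotion(profile, duration, motionRate,
                           seed = childSeed(seed, "motion"))
  strm <- vector("list", length(devices))
  for (i in seq_along(devices)) {
    strm[[i]] <- sampleStream(motion, devices[[i]], clocks[[i]],
                              seed = childSeed(seed, paste0("stream", i)),
                              transportLatency = lat[i],
                              offsetInterval = offsetInterval,
                              offsetNoiseSd = offsetNoiseSd)
  }
  offs <- outer(lat, lat, function(a, b) (b - a) * 1000)
  dimnames(offs) <- list(nms, nms)
  names(lat) <- nms
  new("SimSession", streams = strm,
      groundTruth = list(offsetMs = offs, clocks = clocks,
                         transportLatency = lat, devices = nms),
      duration = duration, seed = seed)
}
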