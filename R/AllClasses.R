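#' @import methods
NULL

#' Per-device clock model
#'
#' Describes how a device's local clock and wireless link distort its view of
#' the shared reference timeline. Raw timestamps follow
#' \code{t_raw = t_ref * (1 + drift) + offset0 + jitter}, while the stream
#' *content* is additionally delayed by a transport latency that the clock
#' synchronization machinery cannot see (it is what perturbation-based
#' calibration estimates). The transport latency is redrawn at each simulated
#' session startup from \code{Normal(transportLatency, transportLatencySd)},
#' truncated at zero, reproducing the large across-restart variability of
#' wireless handshakes.
#'
#' @slot offset0 numeric(1), initial clock offset vs. the shared reference, seconds.
#' @slot drift numeric(1), dimensionless clock-rate error (50 ppm = 5e-5).
#' @slot jitterSd numeric(1), per-sample timestamp noise sd, seconds.
#' @slot transportLatency numeric(1), mean wireless content delay, seconds.
#' @slot transportLatencySd numeric(1), across-startup sd of the latency, seconds.
#' @seealso [clockModel()]
#' @exportClass ClockModel
setClass("ClockModel",
  representation(
    offset0 = "numeric",
    drift = "numeric",
    jitterSd = "numeric",
    transportLatency = "numeric",
    transportLatencySd = "numeric"
  ),
  prototype(offset0 = 0, drift = 0, jitterSd = 0,
            transportLatency = 0, transportLatencySd = 0)
)

setValidity("ClockModel", function(object) {
  msg <- character()
  if (length(object@offset0) != 1L || !is.finite(object@offset0))
    msg <- c(msg, "offset0 must be a finite scalar")
  if (length(object@drift) != 1L || abs(object@drift) >= 1e-3)
    msg <- c(msg, "|drift| must be below 1000 ppm (1e-3)")
  if (object@jitterSd < 0) msg <- c(msg, "jitterSd must be >= 0")
  if (object@transportLatencySd < 0) msg <- c(msg, "transportLatencySd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Device specification
#'
#' @slot name character(1) device identifier.
#' @slot nominalRate numeric(1), sampling rate in Hz.
#' @slot channelLabels character, one label per channel.
#' @slot lossRate numeric(1), per-sample probability of starting a lost run.
#' @slot lossRunMean numeric(1), mean lost-run length in samples (geometric).
#' @seealso [deviceSpec()]
#' @exportClass DeviceSpec
setClass("DeviceSpec",
  representation(
    name = "character",
    nominalRate = "numeric",
    channelLabels = "character",
    lossRate = "numeric",
    lossRunMean = "numeric"
  ),
  prototype(name = "device", nominalRate = 500,
            channelLabels = c("x", "y", "z"), lossRate = 0, lossRunMean = 5)
)

setValidity("DeviceSpec", function(object) {
  msg <- character()
  if (length(object@nominalRate) != 1L || object@nominalRate <= 0)
    msg <- c(msg, "nominalRate must be a positive scalar (Hz)")
  if (object@lossRate < 0 || object@lossRate >= 1)
    msg <- c(msg, "lossRate must lie in [0, 1)")
  if (object@lossRunMean < 1) msg <- c(msg, "lossRunMean must be >= 1 sample")
  if (!length(object@channelLabels)) msg <- c(msg, "at least one channel label")
  if (length(msg)) msg else TRUE
})

#' Mechanical perturbation profile
#'
#' Shared bench perturbations: impulsive strokes (easily re-alignable) plus
#' windows of band-limited random movement, on top of Gaussian baseline noise.
#'
#' @slot nStrokes integer(1), number of strokes; ignored when strokeTimes given.
#' @slot strokeTimes numeric, explicit stroke centres in seconds (length 0 =
#'   schedule randomly at simulation time).
#' @slot strokeWidth numeric(1), stroke half-duration scale, seconds.
#' @slot strokeAmplitude numeric(1), stroke peak amplitude, m/s^2.
#' @slot movementWindows 2-column matrix of (start, end) seconds.
#' @slot movementBandwidth numeric(1), low-pass corner of movement noise, Hz.
#' @slot movementAmplitude numeric(1), RMS of movement segments, m/s^2.
#' @slot baselineNoiseSd numeric(1), baseline noise sd, m/s^2.
#' @seealso [perturbationProfile()], [simulateMotion()]
#' @exportClass PerturbationProfile
setClass("PerturbationProfile",
  representation(
    nStrokes = "integer",
    strokeTimes = "numeric",
    strokeWidth = "numeric",
    strokeAmplitude = "numeric",
    movementWindows = "matrix",
    movementBandwidth = "numeric",
    movementAmplitude = "numeric",
    baselineNoiseSd = "numeric"
  ),
  prototype(nStrokes = 3L, strokeTimes = numeric(), strokeWidth = 0.05,
            strokeAmplitude = 10, movementWindows = matrix(numeric(), ncol = 2),
            movementBandwidth = 8, movementAmplitude = 5, baselineNoiseSd = 0.05)
)

setValidity("PerturbationProfile", function(object) {
  msg <- character()
  if (object@strokeWidth <= 0) msg <- c(msg, "strokeWidth must be > 0")
  if (object@baselineNoiseSd < 0) msg <- c(msg, "baselineNoiseSd must be >= 0")
  if (object@baselineNoiseSd > 0 &&
      object@strokeAmplitude <= 5 * object@baselineNoiseSd)
    msg <- c(msg, "strokeAmplitude must exceed 5 x baselineNoiseSd")
  if (ncol(object@movementWindows) != 2L)
    msg <- c(msg, "movementWindows must have two columns (start, end)")
  if (nrow(object@movementWindows) &&
      any(object@movementWindows[, 2] <= object@movementWindows[, 1]))
    msg <- c(msg, "movement windows must have end > start")
  if (length(msg)) msg else TRUE
})

#' A simulated timestamped stream
#'
#' One device's view of the session: sampled values, raw (device-clock)
#' timestamps, a lost-sample mask and the device's clock-offset measurement
#' history against the collector. \code{sharedTimestamps} is filled by
#' [remapTimestamps()] / [dejitter()].
#'
#' @slot device a [DeviceSpec-class].
#' @slot samples channels x n numeric matrix (lost samples are NA).
#' @slot rawTimestamps numeric n, seconds in the device clock.
#' @slot sharedTimestamps numeric, seconds on the shared timeline (length 0
#'   until remapped).
#' @slot lostMask logical n.
#' @slot offsetHistory matrix with columns time, offset (seconds).
#' @slot meta list (drawn transport latency, applied corrections, ...).
#' @exportClass SimStream
setClass("SimStream",
  representation(
    device = "DeviceSpec",
    samples = "matrix",
    rawTimestamps = "numeric",
    sharedTimestamps = "numeric",
    lostMask = "logical",
    offsetHistory = "matrix",
    meta = "list"
  )
)

setValidity("SimStream", function(object) {
  msg <- character()
  n <- ncol(object@samples)
  if (length(object@rawTimestamps) != n)
    msg <- c(msg, "rawTimestamps length must equal number of samples")
  if (length(object@lostMask) != n)
    msg <- c(msg, "lostMask length must equal number of samples")
  if (length(object@sharedTimestamps) &&
      length(object@sharedTimestamps) != n)
    msg <- c(msg, "sharedTimestamps, when present, must match sample count")
  ok <- object@rawTimestamps[!object@lostMask]
  if (length(ok) > 1 && any(diff(ok) <= 0))
    msg <- c(msg, "raw timestamps must be strictly increasing where not lost")
  if (length(msg)) msg else TRUE
})

#' A simulated multi-device session
#'
#' @slot streams list of [SimStream-class].
#' @slot groundTruth list with elements \code{offsetMs} (pairwise true content
#'   offsets, ms, antisymmetric and additive), \code{clocks} (list of
#'   [ClockModel-class]) and \code{transportLatency} (drawn per-device
#'   latencies, seconds).
#' @slot duration numeric(1), seconds.
#' @slot seed integer(1).
#' @exportClass SimSession
setClass("SimSession",
  representation(
    streams = "list",
    groundTruth = "list",
    duration = "numeric",
    seed = "integer"
  )
)

setValidity("SimSession", function(object) {
  msg <- character()
  if (!all(vapply(object@streams, is, logical(1), "SimStream")))
    msg <- c(msg, "streams must all be SimStream objects")
  gm <- object@groundTruth$offsetMs
  if (!is.null(gm)) {
    if (max(abs(gm + t(gm))) > 1e-9)
      msg <- c(msg, "ground-truth offset matrix must be antisymmetric")
    k <- nrow(gm)
    if (k >= 3) {
      # additivity offset(a,c) = offset(a,b) + offset(b,c)
      for (b in seq_len(k)) {
        d <- outer(gm[, b], gm[b, ], "+")
        if (max(abs(d - gm)) > 1e-9) {
          msg <- c(msg, "ground-truth offsets must be additive")
          break
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Fitted linear clock correction
#'
#' \code{correctedOffset(t) = intercept + slope * t}; shared time is obtained
#' as \code{raw - correctedOffset(raw)}.
#'
#' @slot intercept numeric(1), seconds.
#' @slot slope numeric(1), dimensionless.
#' @slot residualSd numeric(1), sd of measurement residuals, seconds.
#' @slot n integer(1), number of offset measurements used.
#' @exportClass ClockCorrection
setClass("ClockCorrection",
  representation(intercept = "numeric", slope = "numeric",
                 residualSd = "numeric", n = "integer"))

#' Pairwise inter-stream offset matrix
#'
#' Mean and sd of estimated content lags across sessions, in milliseconds,
#' plus the sample-equivalent matrix: \code{samples[i, j] =
#' round(meanMs[i, j] * rate_j / 1000)}.
#'
#' @slot devices character, ordered device names.
#' @slot rates numeric, nominal sampling rate per device (Hz).
#' @slot meanMs,sdMs numeric matrices (ms).
#' @slot samples integer matrix, offsets in samples of the column device.
#' @slot nSessions integer(1).
#' @exportClass OffsetMatrix
setClass("OffsetMatrix",
  representation(devices = "character", rates = "numeric",
                 meanMs = "matrix", sdMs = "matrix",
                 samples = "matrix", nSessions = "integer"))

setValidity("OffsetMatrix", function(object) {
  msg <- character()
  k <- length(object@devices)
  for (sl in c("meanMs", "sdMs", "samples")) {
    m <- slot(object, sl)
    if (!all(dim(m) == k)) msg <- c(msg, sprintf("%s must be %d x %d", sl, k, k))
  }
  if (any(diag(object@meanMs) != 0)) msg <- c(msg, "diagonal of meanMs must be zero")
  if (length(object@rates) != k) msg <- c(msg, "one rate per device required")
  if (length(msg)) msg else TRUE
})

#' Continuous EEG (or generic multichannel) recording
#'
#' @slot data channels x n numeric matrix, microvolts.
#' @slot channels character channel names.
#' @slot sfreq numeric(1), Hz.
#' @slot events data.frame with columns \code{onset} (s) and \code{label}.
#' @slot lostMask logical n, TRUE where samples were lost in transport.
#' @slot blinkPeriod numeric(2), (start, end) seconds of the free-blinking
#'   segment used for blink identification, or length 0.
#' @slot injectionLog data.frame describing injected artifacts (ground truth
#'   for rejection tests): columns kind, start, end, channel.
#' @slot meta list.
#' @exportClass Recording
setClass("Recording",
  representation(
    data = "matrix", channels = "character", sfreq = "numeric",
    events = "data.frame", lostMask = "logical",
    blinkPeriod = "numeric", injectionLog = "data.frame", meta = "list"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channels))
    msg <- c(msg, "one channel name per data row required")
  if (length(object@lostMask) && length(object@lostMask) != ncol(object@data))
    msg <- c(msg, "lostMask must match the number of samples")
  if (length(object@sfreq) != 1L || object@sfreq <= 0)
    msg <- c(msg, "sfreq must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Epoched trials
#'
#' @slot data trials x channels x time numeric array, microvolts.
#' @slot times numeric, seconds relative to the event.
#' @slot channels character channel names.
#' @slot sfreq numeric(1), Hz.
#' @slot labels character, condition per trial.
#' @slot lostMask trials x time logical matrix (transport losses per epoch).
#' @slot rejected logical per trial.
#' @slot rejectReason character per trial; one of loss, amplitude, psd,
#'   linear, manual for rejected trials, NA otherwise.
#' @slot meta list.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    data = "array", times = "numeric", channels = "character",
    sfreq = "numeric", labels = "character", lostMask = "matrix",
    rejected = "logical", rejectReason = "character", meta = "list"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be trials x channels x time")
  else {
    if (length(object@times) != d[3]) msg <- c(msg, "times must match time axis")
    if (length(object@channels) != d[2]) msg <- c(msg, "channels must match data")
    if (length(object@labels) != d[1]) msg <- c(msg, "one label per trial required")
    if (length(object@rejected) != d[1]) msg <- c(msg, "one rejected flag per trial")
    if (length(object@rejectReason) != d[1]) msg <- c(msg, "one rejectReason per trial")
  }
  bad <- object@rejected & is.na(object@rejectReason)
  if (any(bad)) msg <- c(msg, "rejected trials must carry a rejectReason")
  bad2 <- !object@rejected & !is.na(object@rejectReason)
  if (any(bad2)) msg <- c(msg, "kept trials must not carry a rejectReason")
  if (length(msg)) msg else TRUE
})

#' Trial-subsampling power curve
#'
#' @slot nGrid integer trial counts.
#' @slot proportion numeric in [0, 1], fraction of significant subsampling
#'   permutations at each trial count.
#' @slot n80 numeric(1), smallest n with proportion >= target (NA if never).
#' @slot nPerm integer(1).
#' @slot alpha numeric(1) significance level.
#' @slot target numeric(1) power target (default 0.8).
#' @exportClass PowerCurve
setClass("PowerCurve",
  representation(nGrid = "integer", proportion = "numeric", n80 = "numeric",
                 nPerm = "integer", alpha = "numeric", target = "numeric"))

setValidity("PowerCurve", function(object) {
  msg <- character()
  if (length(object@proportion) != length(object@nGrid))
    msg <- c(msg, "one proportion per grid point required")
  if (any(object@proportion < 0 | object@proportion > 1))
    msg <- c(msg, "proportions must lie in [0, 1]")
  if (!is.na(object@n80)) {
    i <- match(object@n80, object@nGrid)
    if (is.na(i) || object@proportion[i] < object@target)
      msg <- c(msg, "n80 must be a grid point whose proportion reaches the target")
  }
  if (length(msg)) msg else TRUE
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "ClockModel", function(object) {
  cat(sprintf(
    "ClockModel: offset0 %.3f ms, drift %.1f ppm, jitter %.3f ms, transport %.1f +/- %.1f ms\n",
    object@offset0 * 1e3, object@drift * 1e6, object@jitterSd * 1e3,
    object@transportLatency * 1e3, object@transportLatencySd * 1e3))
})

setMethod("show", "SimStream", function(object) {
  cat(sprintf("SimStream '%s': %d ch x %d samples @ %g Hz, %d lost, %d offset measurements\n",
              object@device@name, nrow(object@samples), ncol(object@samples),
              object@device@nominalRate, sum(object@lostMask),
              nrow(object@offsetHistory)))
})

setMethod("show", "SimSession", function(object) {
  cat(sprintf("SimSession: %d streams, %.1f s, seed %d\n",
              length(object@streams), object@duration, object@seed))
  for (s in object@streams) show(s)
})

setMethod("show", "OffsetMatrix", function(object) {
  cat(sprintf("OffsetMatrix over %d devices (%d sessions)\n",
              length(object@devices), object@nSessions))
  print(formatOffsetMatrix(object))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d ch x %d samples @ %g Hz, %d events, %d lost samples\n",
              nrow(object@data), ncol(object@data), object@sfreq,
              nrow(object@events), sum(object@lostMask)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d ch x %d samples @ %g Hz; %d rejected\n",
              d[1], d[2], d[3], object@sfreq, sum(object@rejected)))
  if (any(object@rejected))
    print(table(reason = object@rejectReason[object@rejected]))
})

setMethod("show", "PowerCurve", function(object) {
  cat(sprintf("PowerCurve (%d permutations, alpha %.3g): n80 = %s\n",
              object@nPerm, object@alpha,
              ifelse(is.na(object@n80), "not reached", object@n80)))
  print(data.frame(n = object@nGrid, proportion = object@proportion))
})
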