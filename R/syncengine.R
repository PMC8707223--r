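#' Fit a linear clock correction from a clock-offset measurement history
#'
#' The collector measures the momentary clock offset of each device at
#' periodic intervals; a linear model of offset against time captures the
#' initial offset (intercept) and the clock drift (slope). The slope is the
#' Theil-Sen median of pairwise slopes, which tolerates the gross outliers
#' produced by wireless handshake transients; measurements whose residual
#' exceeds \code{outlierK} robust sds are then discarded and the intercept is
#' the least-squares (mean-residual) intercept over the inliers.
#'
#' @param history two-column matrix (time, offset), seconds, or a
#'   [SimStream-class] whose offset history is used.
#' @param outlierK residual cutoff in robust-sd units (default 5).
#' @return a [ClockCorrection-class] with
#'   \code{correctedOffset(t) = intercept + slope * t}.
#' @export
fitClockCorrection <- function(history, outlierK = 5) {
  if (is(history, "SimStream")) history <- history@offsetHistory
  n <- nrow(history)
  if (is.null(n) || n < 2)
    stop("unsynchronizable: need at least 2 clock-offset measurements",
         call. = FALSE)
  t <- history[, 1]
  o <- history[, 2]
  # Theil-Sen: median of all pairwise slopes
  ij <- utils::combn(n, 2)
  slopes <- (o[ij[2, ]] - o[ij[1, ]]) / (t[ij[2, ]] - t[ij[1, ]])
  slope <- stats::median(slopes, na.rm = TRUE)
  resid <- o - slope * t
  mid <- stats::median(resid)
  scale <- max(stats::mad(resid), 1e-6)
  keep <- abs(resid - mid) <= outlierK * scale
  if (sum(keep) < 2) keep <- rep(TRUE, n)
  intercept <- mean(resid[keep])
  new("ClockCorrection", intercept = intercept, slope = slope,
      residualSd = stats::sd(resid[keep]), n = as.integer(sum(keep)))
}

#' Evaluate a clock correction
#'
#' @param correction a [ClockCorrection-class].
#' @param t times, seconds.
#' @return predicted clock offset at \code{t}, seconds.
#' @export
correctedOffset <- function(correction, t) {
  correction@intercept + correction@slope * t
}

#' Remap raw timestamps onto the shared timeline
#'
#' Applies \code{shared = raw - correctedOffset(raw)}. The map is affine and
#' order-preserving (drift is far below 1), so monotonicity is kept. With
#' \code{invert = TRUE} the exact algebraic inverse is applied to the shared
#' timestamps, restoring the raw ones. Transport latency is untouched by
#' design: it is invisible to clock synchronization and is exactly what the
#' perturbation calibration estimates afterwards.
#'
#' @param stream a [SimStream-class].
#' @param correction a [ClockCorrection-class] fitted for this stream
#'   (defaults to fitting from the stream's own offset history).
#' @param invert apply the exact inverse map instead.
#' @return the stream with \code{sharedTimestamps} filled (or, when
#'   inverting, with the raw timestamps restored from them).
#' @export
remapTimestamps <- function(stream, correction = fitClockCorrection(stream),
                            invert = FALSE) {
  if (invert) {
    y <- stream@sharedTimestamps
    stopIfNot(length(y) > 0, "no shared timestamps to invert")
    stream@rawTimestamps <- (y + correction@intercept) / (1 - correction@slope)
    return(stream)
  }
  raw <- stream@rawTimestamps
  stream@sharedTimestamps <- raw - correctedOffset(correction, raw)
  stream@meta$correction <- correction
  stream
}

#' Remove sampling jitter from remapped timestamps
#'
#' Splits the stream into contiguous segments wherever the inter-sample gap
#' exceeds \code{max(2 / nominalRate, 0.010)} seconds, then replaces the
#' timestamps of each segment by the ordinary-least-squares line in sample
#' index, yielding exactly equispaced stamps per segment. The residual sd of
#' the fit is reported in \code{meta$dejitterResidualSd}.
#'
#' @param stream a remapped [SimStream-class].
#' @return the stream with dejittered \code{sharedTimestamps};
#'   \code{meta$segments} holds the segment boundaries.
#' @export
dejitter <- function(stream) {
  ts <- stream@sharedTimestamps
  stopIfNot(length(ts) > 0, "stream must be remapped before dejittering")
  thr <- max(2 / stream@device@nominalRate, 0.010)
  cut <- which(diff(ts) > thr)
  starts <- c(1L, cut + 1L)
  ends <- c(cut, length(ts))
  resid <- numeric()
  for (k in seq_along(starts)) {
    idx <- starts[k]:ends[k]
    if (length(idx) < 2) next
    i <- seq_along(idx)
    fit <- stats::lm.fit(cbind(1, i), ts[idx])
    ts[idx] <- fit$coefficients[1] + fit$coefficients[2] * i
    resid <- c(resid, fit$residuals)
  }
  stream@sharedTimestamps <- ts
  stream@meta$segments <- data.frame(start = starts, end = ends)
  stream@meta$dejitterResidualSd <- if (length(resid) > 1) stats::sd(resid) else 0
  stream
}

#' Detect maximal runs of consecutive lost samples
#'
#' @param stream a [SimStream-class] (or a logical lost mask).
#' @return data.frame with columns \code{start} (index) and \code{length},
#'   sorted by start; zero rows when nothing was lost.
#' @export
detectLostRuns <- function(stream) {
  mask <- if (is(stream, "SimStream")) stream@lostMask else stream
  boolRuns(mask)
}

#' Synchronize every stream of a session
#'
#' Convenience wrapper: fit, remap and dejitter each stream that carries a
#' clock-offset history; streams without one are left untouched and flagged.
#'
#' @param session a [SimSession-class].
#' @return the session with shared, dejittered timestamps per stream.
#' @export
synchronizeSession <- function(session) {
  session@streams <- lapply(session@streams, function(s) {
    if (nrow(s@offsetHistory) < 2) {
      s@meta$unsynchronizable <- TRUE
      return(s)
    }
    dejitter(remapTimestamps(s))
  })
  session
}
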