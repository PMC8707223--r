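#' Rotation-invariant magnitude trace of an accelerometer stream
#'
#' Per-sample Euclidean norm across the 3 axes (or the absolute value of a
#' single-axis stream), mean-removed over non-lost samples. Using the
#' magnitude makes lag estimation insensitive to how each device is oriented
#' on the bench.
#'
#' @param stream a [SimStream-class] with 1 or 3 channels.
#' @return numeric vector (NA where samples were lost).
#' @export
magnitudeTrace <- function(stream) {
  x <- stream@samples
  nch <- nrow(x)
  if (!nch %in% c(1L, 3L))
    stop("magnitude needs a 1- or 3-axis stream, got ", nch, " channels",
         call. = FALSE)
  m <- if (nch == 1L) abs(x[1, ]) else sqrt(colSums(x^2))
  m - mean(m, na.rm = TRUE)
}

#' Resample synchronized streams onto a common grid
#'
#' Linearly interpolates each stream's magnitude trace onto a shared grid
#' (default 1 kHz) spanning the intersection of the streams' time supports.
#' Grid points adjacent to lost samples are marked invalid and excluded from
#' later correlation rather than being interpolated across.
#'
#' @param session a synchronized [SimSession-class] (see
#'   [synchronizeSession()]).
#' @param targetRate common grid rate, Hz (default 1000).
#' @return list with \code{rate}, \code{times} (grid, seconds),
#'   \code{traces} (named list of numeric vectors), \code{valid} (named list
#'   of logicals) and \code{rates} (named device rates).
#' @export
resampleCommon <- function(session, targetRate = 1000) {
  strm <- session@streams
  nms <- devices(session)
  t0 <- max(vapply(strm, function(s) min(s@sharedTimestamps), numeric(1)))
  t1 <- min(vapply(strm, function(s) max(s@sharedTimestamps), numeric(1)))
  if (t1 <= t0)
    stop("streams have no temporal overlap; cannot calibrate", call. = FALSE)
  grid <- seq(ceiling(t0 * targetRate) / targetRate, t1, by = 1 / targetRate)
  traces <- valid <- vector("list", length(strm))
  for (i in seq_along(strm)) {
    s <- strm[[i]]
    stopIfNot(length(s@sharedTimestamps) == ncol(s@samples),
              "stream '%s' must be remapped before resampling", nms[i])
    mg <- magnitudeTrace(s)
    ok <- !s@lostMask
    traces[[i]] <- stats::approx(s@sharedTimestamps[ok], mg[ok], xout = grid,
                                 rule = 2)$y
    lostInd <- stats::approx(s@sharedTimestamps, as.numeric(s@lostMask),
                             xout = grid, rule = 2)$y
    valid[[i]] <- lostInd < 1e-9
  }
  names(traces) <- names(valid) <- nms
  rates <- vapply(strm, function(s) s@device@nominalRate, numeric(1))
  names(rates) <- nms
  list(rate = targetRate, times = grid, traces = traces, valid = valid,
       rates = rates)
}

#' Locate perturbation chunks in a magnitude trace
#'
#' Windows where the 100 ms moving RMS exceeds the trace's median + 10 x MAD;
#' windows closer than 200 ms are merged and windows shorter than 100 ms are
#' dropped.
#'
#' @param trace numeric magnitude trace on the common grid.
#' @param rate grid rate, Hz.
#' @param rmsWindow moving-RMS window, seconds.
#' @param k MAD multiplier of the threshold.
#' @param mergeGap merge windows closer than this, seconds.
#' @param minLength drop windows shorter than this, seconds.
#' @param errorOnEmpty error when nothing is found (the calibration
#'   contract); with FALSE a zero-row data.frame is returned instead.
#' @return data.frame with columns \code{startIndex}, \code{endIndex}
#'   (grid indices, inclusive).
#' @export
findPerturbationChunks <- function(trace, rate = 1000, rmsWindow = 0.1,
                                   k = 10, mergeGap = 0.2, minLength = 0.1,
                                   errorOnEmpty = TRUE) {
  x <- trace
  x[is.na(x)] <- 0
  rms <- movingRms(x, round(rmsWindow * rate))
  thr <- stats::median(rms) + k * stats::mad(rms)
  runs <- boolRuns(rms > thr)
  empty <- data.frame(startIndex = integer(), endIndex = integer())
  if (!nrow(runs)) {
    if (errorOnEmpty)
      stop("no perturbation chunk found; apply a stronger perturbation ",
           "(strokes or movement well above the noise floor)", call. = FALSE)
    return(empty)
  }
  start <- runs$start
  end <- runs$start + runs$length - 1L
  # merge windows separated by less than mergeGap
  keepStart <- start[1]
  ms <- integer()
  me <- integer()
  curEnd <- end[1]
  for (i in seq_along(start)[-1]) {
    if ((start[i] - curEnd) / rate < mergeGap) {
      curEnd <- end[i]
    } else {
      ms <- c(ms, keepStart); me <- c(me, curEnd)
      keepStart <- start[i]; curEnd <- end[i]
    }
  }
  ms <- c(ms, keepStart); me <- c(me, curEnd)
  len <- (me - ms + 1L) / rate
  keep <- len >= minLength
  if (!any(keep)) {
    if (errorOnEmpty)
      stop("all candidate chunks shorter than ", minLength,
           " s; apply a stronger/longer perturbation", call. = FALSE)
    return(empty)
  }
  data.frame(startIndex = ms[keep], endIndex = me[keep])
}

#' Estimate the pairwise lag between two traces by cross-correlation
#'
#' For each perturbation chunk, the chunk segment of \code{ref} is correlated
#' against lag-shifted segments of \code{other} over a +/- \code{maxLagMs}
#' window at the grid resolution (1 ms at 1 kHz; no sub-sample
#' interpolation). The per-chunk lag is the argmax of the normalized
#' cross-correlation; invalid (lost) samples are excluded pairwise rather
#' than interpolated. Positive lag means \code{other} trails \code{ref}: its
#' content arrives later.
#'
#' @param ref,other numeric traces on the common grid.
#' @param chunks data.frame from [findPerturbationChunks()].
#' @param rate grid rate, Hz.
#' @param maxLagMs search half-window, ms.
#' @param validRef,validOther optional logical validity masks.
#' @param combine \code{"mean"} (default) or \code{"median"} across chunks.
#' @return list with \code{lagMs} (combined) and \code{perChunkMs}.
#' @export
estimatePairwiseLag <- function(ref, other, chunks, rate = 1000,
                                maxLagMs = 500, validRef = NULL,
                                validOther = NULL, combine = c("mean", "median")) {
  combine <- match.arg(combine)
  n <- length(ref)
  maxLag <- round(maxLagMs * rate / 1000)
  lags <- seq(-maxLag, maxLag)
  if (is.null(validRef)) validRef <- !is.na(ref)
  if (is.null(validOther)) validOther <- !is.na(other)
  perChunk <- numeric()
  for (ci in seq_len(nrow(chunks))) {
    i1 <- chunks$startIndex[ci]
    i2 <- chunks$endIndex[ci]
    if (i1 - maxLag < 1L || i2 + maxLag > n) {
      warning("chunk ", ci, " too close to the trace edge for a +/-",
              maxLagMs, " ms search; skipped", call. = FALSE)
      next
    }
    idx <- i1:i2
    x <- ref[idx]
    vx <- validRef[idx]
    cc <- vapply(lags, function(L) {
      y <- other[idx + L]
      v <- vx & validOther[idx + L]
      if (sum(v) < 8) return(NA_real_)
      xc <- x[v] - mean(x[v])
      yc <- y[v] - mean(y[v])
      den <- sqrt(sum(xc^2) * sum(yc^2))
      if (den == 0) return(NA_real_)
      sum(xc * yc) / den
    }, numeric(1))
    if (all(is.na(cc))) {
      warning("chunk ", ci, " has no valid overlap; skipped", call. = FALSE)
      next
    }
    perChunk <- c(perChunk, lags[which.max(cc)] * 1000 / rate)
  }
  if (!length(perChunk))
    stop("every chunk was skipped; cannot estimate the lag", call. = FALSE)
  lag <- if (combine == "mean") mean(perChunk) else stats::median(perChunk)
  list(lagMs = lag, perChunkMs = perChunk)
}

#' Estimate all pairwise lags of one session
#'
#' Synchronizes the session if needed, resamples all magnitude traces to the
#' common grid, finds perturbation chunks on each reference trace, and
#' estimates the lag of every ordered device pair (both directions are
#' estimated independently, so residual asymmetry is measurable).
#'
#' @param session a [SimSession-class].
#' @param targetRate common grid rate, Hz.
#' @param ... passed to [estimatePairwiseLag()].
#' @return k x k matrix of lags in ms (row = reference, col = other).
#' @export
sessionLagMatrix <- function(session, targetRate = 1000, ...) {
  if (!length(session@streams[[1]]@sharedTimestamps))
    session <- synchronizeSession(session)
  rs <- resampleCommon(session, targetRate)
  nms <- names(rs$traces)
  k <- length(nms)
  lag <- matrix(0, k, k, dimnames = list(nms, nms))
  chunks <- lapply(nms, function(nm)
    findPerturbationChunks(rs$traces[[nm]], rate = rs$rate))
  names(chunks) <- nms
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    est <- estimatePairwiseLag(rs$traces[[i]], rs$traces[[j]], chunks[[i]],
                               rate = rs$rate, validRef = rs$valid[[i]],
                               validOther = rs$valid[[j]], ...)
    lag[i, j] <- est$lagMs
  }
  lag
}

#' Build the offset matrix from per-session lag matrices
#'
#' Averages pairwise lags across sessions (cold restarts), reports the sample
#' sd, antisymmetrizes the mean as \code{(m - t(m)) / 2}, and converts the
#' mean to samples of the column device:
#' \code{samples[i, j] = round(meanMs[i, j] * rate_j / 1000)}.
#'
#' @param sessionLags list of k x k lag matrices (ms), one per session.
#' @param rates named numeric, nominal rate per device (Hz).
#' @return an [OffsetMatrix-class].
#' @export
buildOffsetMatrix <- function(sessionLags, rates) {
  stopIfNot(length(sessionLags) >= 1, "need at least one session")
  nms <- rownames(sessionLags[[1]])
  rates <- rates[nms]
  arr <- simplify2array(sessionLags)
  if (length(sessionLags) == 1L) {
    warning("single session: sd reported as 0", call. = FALSE)
    m <- sessionLags[[1]]
    s <- m * 0
  } else {
    m <- apply(arr, c(1, 2), mean)
    s <- apply(arr, c(1, 2), stats::sd)
  }
  m <- (m - t(m)) / 2
  diag(m) <- 0
  smp <- round(sweep(m, 2, rates / 1000, "*"))
  storage.mode(smp) <- "integer"
  dimnames(m) <- dimnames(s) <- dimnames(smp) <- list(nms, nms)
  new("OffsetMatrix", devices = nms, rates = as.numeric(rates),
      meanMs = m, sdMs = s, samples = smp,
      nSessions = length(sessionLags))
}

#' Compensate streams for the calibrated transport offsets
#'
#' Shifts each stream's shared-time timestamps by \code{-meanMs[ref, device]}
#' so content aligns with the reference device; the applied correction is
#' recorded in the stream metadata.
#'
#' @param session a synchronized [SimSession-class].
#' @param matrix an [OffsetMatrix-class] covering all the session's devices.
#' @param refDevice reference device name.
#' @return the compensated session.
#' @export
compensateStreams <- function(session, matrix, refDevice) {
  nms <- devices(session)
  stopIfNot(refDevice %in% matrix@devices,
            "reference device '%s' missing from the offset matrix", refDevice)
  missing <- setdiff(nms, matrix@devices)
  if (length(missing))
    stop("devices missing from the offset matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (i in seq_along(session@streams)) {
    off <- matrix@meanMs[refDevice, nms[i]] / 1000
    s <- session@streams[[i]]
    s@sharedTimestamps <- s@sharedTimestamps - off
    s@meta$appliedOffsetMs <- (s@meta$appliedOffsetMs %||% 0) +
      matrix@meanMs[refDevice, nms[i]]
    session@streams[[i]] <- s
  }
  session
}

#' Write a Table-style offset report
#'
#' CSV mirroring the bench characterization table: upper triangle of
#' "mean +/- sd [samples]" entries.
#'
#' @param matrix an [OffsetMatrix-class].
#' @param path output CSV path.
#' @return path, invisibly.
#' @export
writeOffsetReport <- function(matrix, path) {
  k <- length(matrix@devices)
  txt <- formatOffsetMatrix(matrix)
  txt[lower.tri(txt)] <- ""
  df <- data.frame(device = matrix@devices, txt, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
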