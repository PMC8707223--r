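#' Write / read a session container
#'
#' Sessions are stored as a single self-describing JSON document holding one
#' object per stream (device spec, samples, raw/shared timestamps, lost mask,
#' clock-offset measurement history) plus the simulation ground truth when
#' present. Numbers are written at full precision so the round-trip is
#' lossless; lost samples are stored as nulls. Files written by other tools
#' are accepted as long as they provide the same stream fields; a stream
#' lacking a clock-offset history is read but flagged unsynchronizable.
#'
#' @param session a [SimSession-class].
#' @param path file path (conventionally \code{.session.json}).
#' @return \code{writeSession} returns \code{path} invisibly;
#'   \code{readSession} returns a [SimSession-class].
#' @export
writeSession <- function(session, path) {
  enc <- list(
    format = "synclab-session", version = 1L,
    duration = session@duration, seed = session@seed,
    streams = lapply(session@streams, encodeStream),
    groundTruth = encodeGroundTruth(session@groundTruth)
  )
  jsonlite::write_json(enc, path, digits = NA, auto_unbox = TRUE,
                       na = "null", pretty = FALSE)
  invisible(path)
}

encodeStream <- function(s) {
  list(
    name = s@device@name,
    nominalRate = s@device@nominalRate,
    channelLabels = as.list(s@device@channelLabels),
    lossRate = s@device@lossRate,
    lossRunMean = s@device@lossRunMean,
    samples = apply(s@samples, 1, identity, simplify = FALSE),
    rawTimestamps = s@rawTimestamps,
    sharedTimestamps = s@sharedTimestamps,
    lostMask = s@lostMask,
    offsetTime = s@offsetHistory[, 1],
    offsetValue = s@offsetHistory[, 2],
    transportLatency = s@meta$transportLatency
  )
}

encodeGroundTruth <- function(gt) {
  if (is.null(gt$offsetMs)) return(NULL)
  list(
    devices = as.list(gt$devices),
    offsetMs = apply(gt$offsetMs, 1, identity, simplify = FALSE),
    transportLatency = as.numeric(gt$transportLatency),
    clocks = lapply(gt$clocks, function(cl) list(
      offset0 = cl@offset0, driftPpm = cl@drift * 1e6, jitterSd = cl@jitterSd,
      transportLatency = cl@transportLatency,
      transportLatencySd = cl@transportLatencySd))
  )
}

#' @rdname writeSession
#' @export
readSession <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse session file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(doc$format, "synclab-session"))
    stop("'", path, "' is not a session container (missing format tag)",
         call. = FALSE)
  streams <- lapply(seq_along(doc$streams), function(i)
    decodeStream(doc$streams[[i]], i))
  gt <- decodeGroundTruth(doc$groundTruth)
  new("SimSession", streams = streams, groundTruth = gt,
      duration = as.numeric(doc$duration),
      seed = as.integer(doc$seed %||% 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

numv <- function(x) vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                           numeric(1))

decodeStream <- function(s, i) {
  name <- s$name %||% sprintf("stream%d", i)
  for (f in c("samples", "rawTimestamps", "lostMask"))
    if (is.null(s[[f]]))
      stop(sprintf("stream '%s' is malformed: missing field '%s'", name, f),
           call. = FALSE)
  samples <- do.call(rbind, lapply(s$samples, numv))
  dev <- deviceSpec(name,
                    nominalRate = as.numeric(s$nominalRate %||% 500),
                    channelLabels = as.character(unlist(s$channelLabels %||%
                      paste0("ch", seq_len(nrow(samples))))),
                    lossRate = as.numeric(s$lossRate %||% 0),
                    lossRunMean = as.numeric(s$lossRunMean %||% 5))
  hist <- cbind(time = numv(s$offsetTime), offset = numv(s$offsetValue))
  meta <- list(transportLatency = as.numeric(s$transportLatency %||% NA_real_))
  if (nrow(hist) == 0L) {
    meta$unsynchronizable <- TRUE
    warning("stream '", name, "' has no clock-offset history; ",
            "flagged unsynchronizable", call. = FALSE)
  }
  new("SimStream", device = dev, samples = samples,
      rawTimestamps = numv(s$rawTimestamps),
      sharedTimestamps = numv(s$sharedTimestamps %||% list()),
      lostMask = vapply(s$lostMask, isTRUE, logical(1)),
      offsetHistory = hist, meta = meta)
}

decodeGroundTruth <- function(g) {
  if (is.null(g)) return(list())
  devs <- as.character(unlist(g$devices))
  offs <- do.call(rbind, lapply(g$offsetMs, numv))
  dimnames(offs) <- list(devs, devs)
  lat <- numv(g$transportLatency)
  names(lat) <- devs
  clocks <- lapply(g$clocks, function(cl)
    clockModel(offset0 = as.numeric(cl$offset0),
               driftPpm = as.numeric(cl$driftPpm),
               jitterSd = as.numeric(cl$jitterSd),
               transportLatency = as.numeric(cl$transportLatency),
               transportLatencySd = as.numeric(cl$transportLatencySd)))
  list(offsetMs = offs, clocks = clocks, transportLatency = lat,
       devices = devs)
}
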