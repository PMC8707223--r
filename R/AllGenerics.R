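#' Accessors
#'
#' Small accessor generics for the package's containers, so downstream code
#' never touches slots directly.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("streams", function(x) standardGeneric("streams"))
#' @rdname accessors
#' @export
setMethod("streams", "SimSession", function(x) x@streams)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "SimSession", function(x) x@groundTruth)

#' @rdname accessors
#' @export
setGeneric("devices", function(x) standardGeneric("devices"))
#' @rdname accessors
#' @export
setMethod("devices", "SimSession", function(x)
  vapply(x@streams, function(s) s@device@name, character(1)))
#' @rdname accessors
#' @export
setMethod("devices", "OffsetMatrix", function(x) x@devices)

#' @rdname accessors
#' @export
setGeneric("meanMs", function(x) standardGeneric("meanMs"))
#' @rdname accessors
#' @export
setMethod("meanMs", "OffsetMatrix", function(x) x@meanMs)

#' @rdname accessors
#' @export
setGeneric("sdMs", function(x) standardGeneric("sdMs"))
#' @rdname accessors
#' @export
setMethod("sdMs", "OffsetMatrix", function(x) x@sdMs)

#' @rdname accessors
#' @export
setGeneric("offsetSamples", function(x) standardGeneric("offsetSamples"))
#' @rdname accessors
#' @export
setMethod("offsetSamples", "OffsetMatrix", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("sfreq", function(x) standardGeneric("sfreq"))
#' @rdname accessors
#' @export
setMethod("sfreq", "Recording", function(x) x@sfreq)
#' @rdname accessors
#' @export
setMethod("sfreq", "EpochSet", function(x) x@sfreq)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "Recording", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channels)

#' @rdname accessors
#' @export
setGeneric("recordingEvents", function(x) standardGeneric("recordingEvents"))
#' @rdname accessors
#' @export
setMethod("recordingEvents", "Recording", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("injectionLog", function(x) standardGeneric("injectionLog"))
#' @rdname accessors
#' @export
setMethod("injectionLog", "Recording", function(x) x@injectionLog)

#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))
#' @rdname accessors
#' @export
setMethod("epochTimes", "EpochSet", function(x) x@times)

#' @rdname accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))
#' @rdname accessors
#' @export
setMethod("trialLabels", "EpochSet", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("rejected", function(x) standardGeneric("rejected"))
#' @rdname accessors
#' @export
setMethod("rejected", "EpochSet", function(x) x@rejected)

#' @rdname accessors
#' @export
setGeneric("rejectReason", function(x) standardGeneric("rejectReason"))
#' @rdname accessors
#' @export
setMethod("rejectReason", "EpochSet", function(x) x@rejectReason)

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1])

#' @rdname accessors
#' @export
setGeneric("n80", function(x) standardGeneric("n80"))
#' @rdname accessors
#' @export
setMethod("n80", "PowerCurve", function(x) x@n80)

#' @rdname accessors
#' @export
setGeneric("powerProportion", function(x) standardGeneric("powerProportion"))
#' @rdname accessors
#' @export
setMethod("powerProportion", "PowerCurve", function(x) x@proportion)

#' @rdname accessors
#' @export
setGeneric("powerGrid", function(x) standardGeneric("powerGrid"))
#' @rdname accessors
#' @export
setMethod("powerGrid", "PowerCurve", function(x) x@nGrid)

#' Keep only accepted trials
#'
#' @param x an [EpochSet-class].
#' @return an [EpochSet-class] containing only non-rejected trials.
#' @export
setGeneric("acceptedTrials", function(x) standardGeneric("acceptedTrials"))
#' @rdname acceptedTrials
#' @export
setMethod("acceptedTrials", "EpochSet", function(x) {
  keep <- !x@rejected
  newEpochSet(x@data[keep, , , drop = FALSE], x@times, x@channels, x@sfreq,
              x@labels[keep], x@lostMask[keep, , drop = FALSE], meta = x@meta)
})
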