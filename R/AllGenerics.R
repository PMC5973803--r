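#' @rdname SpikeTrain
#' @param object,x a package object.
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))

#' @rdname SpikeTrain
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname SpikeTrain
#' @export
setGeneric("recordingDuration",
           function(x) standardGeneric("recordingDuration"))

#' @rdname Session
#' @export
setGeneric("sessionUnits", function(x) standardGeneric("sessionUnits"))

#' @rdname Session
#' @export
setGeneric("sessionEvents", function(x) standardGeneric("sessionEvents"))

#' @rdname Session
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname Psth
#' @export
setGeneric("psthCounts", function(x) standardGeneric("psthCounts"))

#' @rdname Psth
#' @export
setGeneric("meanRatePerBin", function(x) standardGeneric("meanRatePerBin"))

#' @rdname Psth
#' @export
setGeneric("ciBand", function(x) standardGeneric("ciBand"))

setMethod("unitId", "SpikeTrain", function(x) x@unitId)
setMethod("spikeTimes", "SpikeTrain", function(x) x@spikeTimes)
setMethod("recordingDuration", "SpikeTrain", function(x) x@duration)
setMethod("unitId", "DetectionResult", function(x) x@unitId)
setMethod("sessionUnits", "Session", function(x) x@units)
setMethod("sessionEvents", "Session", function(x) x@events)
setMethod("condition", "Session", function(x) x@condition)
setMethod("psthCounts", "Psth", function(x) x@counts)

#' @rdname Psth
#' @aliases meanRatePerBin,Psth-method
setMethod("meanRatePerBin", "Psth", function(x) {
  colSums(x@counts) / (x@nTrials * x@binWidth)
})

#' @rdname Psth
#' @aliases ciBand,Psth-method
setMethod("ciBand", "Psth", function(x) {
  c(lower = x@ciLower, upper = x@ciUpper)
})
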