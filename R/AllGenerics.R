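#' Accessors for Frame and LabelMask
#'
#' `frameData()` returns the raw intensity (or label) matrix,
#' `pixelSize()` the calibration in um/px, `channelName()` the channel
#' tag and `timePoint()` the acquisition time.
#'
#' @param object a [Frame-class] or [LabelMask-class]
#' @return the corresponding slot value
#' @name frame-accessors
NULL

#' @rdname frame-accessors
#' @export
setGeneric("frameData", function(object) standardGeneric("frameData"))
#' @rdname frame-accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname frame-accessors
#' @export
setGeneric("channelName", function(object) standardGeneric("channelName"))
#' @rdname frame-accessors
#' @export
setGeneric("timePoint", function(object) standardGeneric("timePoint"))
#' @rdname frame-accessors
#' @export
setGeneric("objectCount", function(object) standardGeneric("objectCount"))

#' @rdname frame-accessors
setMethod("frameData", "Frame", function(object) object@data)
#' @rdname frame-accessors
setMethod("frameData", "LabelMask", function(object) object@data)
#' @rdname frame-accessors
setMethod("pixelSize", "Frame", function(object) object@pixelSize)
#' @rdname frame-accessors
setMethod("pixelSize", "LabelMask", function(object) object@pixelSize)
#' @rdname frame-accessors
setMethod("channelName", "Frame", function(object) object@channel)
#' @rdname frame-accessors
setMethod("timePoint", "Frame", function(object) object@timepoint)
#' @rdname frame-accessors
setMethod("objectCount", "LabelMask", function(object) max(object@data))
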