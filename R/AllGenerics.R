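#' @rdname FrameSequence-class
#' @param x,object an object of the documented class
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname FrameSequence-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FrameSequence-class
#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))

#' @rdname FrameSequence-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname SecondaryDiff-class
#' @export
setGeneric("diffIndex", function(x) standardGeneric("diffIndex"))

#' @rdname SecondaryDiff-class
#' @export
setGeneric("diffRaster", function(x) standardGeneric("diffRaster"))

#' @rdname BinaryMask-class
#' @export
setGeneric("maskRaster", function(x) standardGeneric("maskRaster"))

#' @rdname BinaryMask-class
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))

#' @rdname MeasurementSet-class
#' @export
setGeneric("individualId", function(x) standardGeneric("individualId"))

#' @rdname MeasurementSet-class
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))

#' @rdname MeasurementSet-class
#' @export
setGeneric("maxM", function(x) standardGeneric("maxM"))

#' @rdname FilterConfig-class
#' @export
setGeneric("criticalRatio", function(x) standardGeneric("criticalRatio"))

#' @rdname CalibrationModel-class
#' @export
setGeneric("calSlope", function(x) standardGeneric("calSlope"))

#' @rdname CalibrationModel-class
#' @export
setGeneric("calIntercept", function(x) standardGeneric("calIntercept"))

#' @rdname CalibrationModel-class
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname BodyLengthEstimate-class
#' @export
setGeneric("bodyLength", function(x) standardGeneric("bodyLength"))

#' @rdname BodyLengthEstimate-class
#' @export
setGeneric("keptRecords", function(x) standardGeneric("keptRecords"))

#' @rdname GroundTruth-class
#' @export
setGeneric("trueLength", function(x) standardGeneric("trueLength"))

#' @rdname GroundTruth-class
#' @export
setGeneric("poses", function(x) standardGeneric("poses"))

#' @rdname GroundTruth-class
#' @export
setGeneric("debris", function(x) standardGeneric("debris"))
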