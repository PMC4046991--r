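# Accessors and show methods. Slots are implementation detail; these are the
# supported surface.

#' @rdname FrameSequence-class
#' @export
setMethod("frames", "FrameSequence", function(x) x@frames)

#' @rdname FrameSequence-class
#' @export
setMethod("nFrames", "FrameSequence", function(x) length(x@frames))

#' @rdname FrameSequence-class
#' @export
setMethod("pixelScale", "FrameSequence", function(x) x@pixelScaleMm)

#' @rdname FrameSequence-class
#' @export
setMethod("frameInterval", "FrameSequence", function(x) x@intervalS)

setMethod("show", "FrameSequence", function(object) {
    d <- dim(object@frames[[1L]])
    cat(sprintf(
        "FrameSequence: %d frames of %d x %d px (%.1f x %.1f mm at %.4g mm/px), %g s apart\n",
        length(object@frames), d[1L], d[2L],
        d[1L] * object@pixelScaleMm, d[2L] * object@pixelScaleMm,
        object@pixelScaleMm, object@intervalS))
})

#' @rdname SecondaryDiff-class
#' @export
setMethod("diffIndex", "SecondaryDiff", function(x) x@index)

#' @rdname SecondaryDiff-class
#' @export
setMethod("diffRaster", "SecondaryDiff", function(x) x@raster)

setMethod("show", "SecondaryDiff", function(object) {
    cat(sprintf("SecondaryDiff of central frame %d: %d x %d px, max magnitude %.4f\n",
                object@index, nrow(object@raster), ncol(object@raster),
                max(object@raster)))
})

#' @rdname BinaryMask-class
#' @export
setMethod("maskRaster", "BinaryMask", function(x) x@mask)

#' @rdname BinaryMask-class
#' @export
setMethod("thresholdUsed", "BinaryMask", function(x) x@thresholdUsed)

setMethod("show", "BinaryMask", function(object) {
    cat(sprintf("BinaryMask: %d of %d px above threshold %.4f\n",
                sum(object@mask), length(object@mask), object@thresholdUsed))
})

#' @rdname MeasurementSet-class
#' @export
setMethod("individualId", "MeasurementSet", function(x) x@individualId)

#' @rdname MeasurementSet-class
#' @export
setMethod("measurements", "MeasurementSet", function(x) x@records)

#' @rdname MeasurementSet-class
#' @export
setMethod("maxM", "MeasurementSet", function(x) {
    if (nrow(x@records) == 0L) stop("empty MeasurementSet has no maximum M")
    max(x@records$majorMm)
})

setMethod("show", "MeasurementSet", function(object) {
    cat(sprintf("MeasurementSet '%s': %d M records", object@individualId,
                nrow(object@records)))
    if (nrow(object@records) > 0L)
        cat(sprintf(", max M = %.4f mm", max(object@records$majorMm)))
    cat("\n")
})

#' @rdname FilterConfig-class
#' @export
setMethod("criticalRatio", "FilterConfig", function(x) x@criticalRatio)

#' @rdname CalibrationModel-class
#' @export
setMethod("calSlope", "CalibrationModel", function(x) x@slope)

#' @rdname CalibrationModel-class
#' @export
setMethod("calIntercept", "CalibrationModel", function(x) x@intercept)

#' @rdname CalibrationModel-class
#' @export
setMethod("rSquared", "CalibrationModel", function(x) x@rSquared)

#' @describeIn CalibrationModel-class coefficients as c(intercept, slope),
#'   the ordering \code{stats::coef} uses for a simple linear model.
#' @export
setMethod("coef", "CalibrationModel", function(object)
    c(intercept = object@intercept, slope = object@slope))

setMethod("show", "CalibrationModel", function(object) {
    cat(sprintf("CalibrationModel: body length = %.4g x M %+.4g mm",
                object@slope, object@intercept))
    if (!is.na(object@rSquared))
        cat(sprintf(" (R^2 = %.3f)", object@rSquared))
    cat("\n")
})

#' @rdname BodyLengthEstimate-class
#' @export
setMethod("individualId", "BodyLengthEstimate", function(x) x@individualId)

#' @rdname BodyLengthEstimate-class
#' @export
setMethod("bodyLength", "BodyLengthEstimate", function(x) x@lengthMm)

#' @rdname BodyLengthEstimate-class
#' @export
setMethod("keptRecords", "BodyLengthEstimate", function(x) x@keptRecords)

#' @describeIn BodyLengthEstimate-class number of M records before (nRaw)
#'   and after (nKept) the critical-ratio filter.
#' @export
nRaw <- function(x) {
    stopifnot(is(x, "BodyLengthEstimate"))
    x@nRaw
}

#' @rdname BodyLengthEstimate-class
#' @export
nKept <- function(x) {
    stopifnot(is(x, "BodyLengthEstimate"))
    x@nKept
}

setMethod("show", "BodyLengthEstimate", function(object) {
    cat(sprintf("BodyLengthEstimate '%s': %.4f mm (from %d of %d M records)\n",
                object@individualId, object@lengthMm, object@nKept,
                object@nRaw))
})

#' @rdname GroundTruth-class
#' @export
setMethod("trueLength", "GroundTruth", function(x) x@trueLengthMm)

#' @rdname GroundTruth-class
#' @export
setMethod("poses", "GroundTruth", function(x) x@poses)

#' @rdname GroundTruth-class
#' @export
setMethod("debris", "GroundTruth", function(x) x@debris)

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %.4f mm animal, %d poses, %d debris specks\n",
                object@trueLengthMm, nrow(object@poses), nrow(object@debris)))
})

setMethod("show", "SceneConfig", function(object) {
    cat(sprintf("SceneConfig: %d frames of %d x %d px, %.3g mm animal (seed %d)\n",
                object@nFrames, object@imageSizePx[1L], object@imageSizePx[2L],
                object@animalLengthMm, object@seed))
})
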