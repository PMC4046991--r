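#' @import methods
NULL

#' FrameSequence: an ordered capture series of one individual
#'
#' Ordered, equal-sized grayscale intensity rasters of a single animal
#' photographed at fixed intervals on a fixed background, together with the
#' physical pixel scale. Intensities are normalized to [0, 1]. The capture
#' protocol this models takes ten consecutive frames over 30 seconds at
#' 3-second intervals, at 24.6 micrometers per pixel.
#'
#' @slot frames list of numeric matrices (row x col), all the same size,
#'   values in [0, 1].
#' @slot pixelScaleMm mm per pixel edge (> 0); default 0.0246.
#' @slot intervalS seconds between consecutive frames (metadata only).
#' @name FrameSequence-class
#' @aliases FrameSequence-class
#' @exportClass FrameSequence
setClass("FrameSequence",
         representation(frames = "list",
                        pixelScaleMm = "numeric",
                        intervalS = "numeric"),
         prototype(frames = list(), pixelScaleMm = 0.0246, intervalS = 3))

setValidity("FrameSequence", function(object) {
    f <- object@frames
    if (length(f) < 1L)
        return("a FrameSequence needs at least one frame")
    if (!all(vapply(f, is.matrix, logical(1L))))
        return("all frames must be 2-D numeric matrices (use toGrayscale() first)")
    d <- dim(f[[1L]])
    if (!all(vapply(f, function(x) identical(dim(x), d), logical(1L))))
        return("all frames must share identical dimensions")
    rng <- range(vapply(f, function(x) range(x), numeric(2L)))
    if (rng[1L] < 0 || rng[2L] > 1)
        return("frame intensities must lie in [0, 1]")
    if (length(object@pixelScaleMm) != 1L || !is.finite(object@pixelScaleMm) ||
        object@pixelScaleMm <= 0)
        return("pixelScaleMm must be a single positive number")
    if (length(object@intervalS) != 1L || object@intervalS <= 0)
        return("intervalS must be a single positive number")
    TRUE
})

#' SecondaryDiff: motion-difference raster for one interior frame
#'
#' The pixelwise minimum of |frame_t - frame_(t-1)| and |frame_t -
#' frame_(t+1)|. A pixel is bright only where the central frame differs from
#' BOTH neighbours, which isolates the animal's position at time t and
#' cancels the static background as well as the ghost positions at t-1 and
#' t+1.
#'
#' @slot index 1-based index of the central frame in the source sequence.
#' @slot raster numeric matrix of non-negative difference magnitudes.
#' @name SecondaryDiff-class
#' @aliases SecondaryDiff-class
#' @exportClass SecondaryDiff
setClass("SecondaryDiff",
         representation(index = "integer", raster = "matrix"))

setValidity("SecondaryDiff", function(object) {
    if (length(object@index) != 1L || object@index < 2L)
        return("index must be a single interior-frame index (>= 2)")
    if (any(object@raster < 0))
        return("difference magnitudes must be non-negative")
    TRUE
})

#' BinaryMask: thresholded secondary difference image
#'
#' @slot mask logical matrix, TRUE strictly above the threshold.
#' @slot thresholdUsed the intensity cutoff that was applied.
#' @name BinaryMask-class
#' @aliases BinaryMask-class
#' @exportClass BinaryMask
setClass("BinaryMask",
         representation(mask = "matrix", thresholdUsed = "numeric"))

setValidity("BinaryMask", function(object) {
    if (!is.logical(object@mask))
        return("mask must be a logical matrix")
    if (length(object@thresholdUsed) != 1L)
        return("thresholdUsed must be a single number")
    TRUE
})

#' AreaGate: physical-area inclusion range for particles
#'
#' Particles whose pixel area falls outside [minMm2, maxMm2] (inclusive) are
#' excluded from analysis; the defaults, 0.01 and 10 mm^2, separate the
#' animal from dust specks and large artifacts.
#'
#' @slot minMm2 lower inclusive bound in mm^2.
#' @slot maxMm2 upper inclusive bound in mm^2.
#' @name AreaGate-class
#' @aliases AreaGate-class
#' @exportClass AreaGate
setClass("AreaGate",
         representation(minMm2 = "numeric", maxMm2 = "numeric"),
         prototype(minMm2 = 0.01, maxMm2 = 10))

setValidity("AreaGate", function(object) {
    if (!(object@minMm2 > 0 && object@minMm2 < object@maxMm2))
        return("need 0 < minMm2 < maxMm2")
    TRUE
})

#' FilterConfig: critical-ratio filter settings
#'
#' M records smaller than criticalRatio times the individual's largest M are
#' discarded as artifacts of insufficient movement or irregular posture. The
#' default, 0.939, is the published instrument value (93.9% of the maximum).
#'
#' @slot criticalRatio fraction in (0, 1].
#' @name FilterConfig-class
#' @aliases FilterConfig-class
#' @exportClass FilterConfig
setClass("FilterConfig",
         representation(criticalRatio = "numeric"),
         prototype(criticalRatio = 0.939))

setValidity("FilterConfig", function(object) {
    cr <- object@criticalRatio
    if (length(cr) != 1L || !is.finite(cr) || cr <= 0 || cr > 1)
        return("criticalRatio must be a single value in (0, 1]")
    TRUE
})

#' CalibrationModel: affine map from ellipse major axis to body length
#'
#' body length = slope * M + intercept. The defaults (slope 0.930, intercept
#' -0.070 mm) are the published instrument constants; the slope below one
#' and negative intercept correct the overestimation of the fitted ellipse,
#' which takes protruding appendages into account.
#'
#' @slot slope mm of body length per mm of M (> 0).
#' @slot intercept mm.
#' @slot rSquared coefficient of determination of the fit (NA if not fitted).
#' @name CalibrationModel-class
#' @aliases CalibrationModel-class
#' @exportClass CalibrationModel
setClass("CalibrationModel",
         representation(slope = "numeric", intercept = "numeric",
                        rSquared = "numeric"),
         prototype(slope = 0.930, intercept = -0.070, rSquared = NA_real_))

setValidity("CalibrationModel", function(object) {
    if (length(object@slope) != 1L || !is.finite(object@slope) ||
        object@slope <= 0)
        return("slope must be a single positive number")
    if (length(object@intercept) != 1L || !is.finite(object@intercept))
        return("intercept must be a single finite number")
    TRUE
})

#' MeasurementSet: all M values collected for one individual
#'
#' One row per segmented patch ("each row corresponding to one patch");
#' a ten-frame sequence nominally yields eight rows, but there can be more
#' (split patches when the animal moves too little) or fewer (no patch when
#' it does not move at all).
#'
#' @slot individualId opaque label.
#' @slot records data.frame with columns frameIndex (integer, central-frame
#'   index) and majorMm (positive numeric).
#' @name MeasurementSet-class
#' @aliases MeasurementSet-class
#' @exportClass MeasurementSet
setClass("MeasurementSet",
         representation(individualId = "character", records = "data.frame"))

setValidity("MeasurementSet", function(object) {
    r <- object@records
    if (!all(c("frameIndex", "majorMm") %in% names(r)))
        return("records needs columns frameIndex and majorMm")
    if (nrow(r) > 0L && any(!is.finite(r$majorMm) | r$majorMm <= 0))
        return("all majorMm must be positive and finite")
    TRUE
})

#' BodyLengthEstimate: one calibrated length per individual
#'
#' @slot individualId opaque label.
#' @slot lengthMm mean of the filtered, calibrated M values.
#' @slot nRaw number of M records before filtering.
#' @slot nKept number of M records surviving the critical-ratio filter.
#' @slot keptRecords the surviving (frameIndex, majorMm) rows.
#' @name BodyLengthEstimate-class
#' @aliases BodyLengthEstimate-class
#' @exportClass BodyLengthEstimate
setClass("BodyLengthEstimate",
         representation(individualId = "character", lengthMm = "numeric",
                        nRaw = "integer", nKept = "integer",
                        keptRecords = "data.frame"))

setValidity("BodyLengthEstimate", function(object) {
    if (object@nKept < 1L || object@nKept > object@nRaw)
        return("need 1 <= nKept <= nRaw")
    TRUE
})

#' SceneConfig: parameters of the synthetic capture scene
#'
#' Describes a backlit field of view with one capsule-shaped animal (dark on
#' a bright background), immobile debris specks, and i.i.d. Gaussian sensor
#' noise. The defaults emulate the imaging device: a 48 x 37 mm field at
#' 24.6 micrometers per pixel (1504 x 1940 px), ten frames.
#'
#' @slot imageSizePx integer (rows, cols).
#' @slot pixelScaleMm mm per pixel edge.
#' @slot nFrames number of frames (>= 3).
#' @slot animalLengthMm ground-truth end-to-end body length.
#' @slot animalWidthMm capsule width (< length).
#' @slot appendageLengthMm length of thin antenna-like protrusions at the
#'   head end (0 disables them).
#' @slot stepPx per-frame displacement magnitude; NA picks the smallest
#'   displacement compatible with \code{allowOverlap}.
#' @slot allowOverlap if FALSE, consecutive (and next-nearest) poses are
#'   kept disjoint so every secondary difference shows one whole patch.
#' @slot nDebris number of static debris specks.
#' @slot debrisAreaRangeMm2 (min, max) speck area in mm^2.
#' @slot noiseSd Gaussian intensity noise sigma (per pixel, per frame).
#' @slot backgroundLevel,animalLevel,debrisLevel rendered intensities.
#' @slot curl per-frame bending of the body along a circular arc, as the
#'   fraction of a half-turn (0 = straight); recycled over frames.
#' @slot staticAnimal render the animal at the same pose in every frame
#'   (a scene in which motion segmentation must find nothing).
#' @slot seed integer RNG seed; mandatory, there is no implicit randomness.
#' @name SceneConfig-class
#' @aliases SceneConfig-class
#' @exportClass SceneConfig
setClass("SceneConfig",
         representation(imageSizePx = "integer", pixelScaleMm = "numeric",
                        nFrames = "integer", animalLengthMm = "numeric",
                        animalWidthMm = "numeric", appendageLengthMm = "numeric",
                        stepPx = "numeric", allowOverlap = "logical",
                        nDebris = "integer", debrisAreaRangeMm2 = "numeric",
                        noiseSd = "numeric", backgroundLevel = "numeric",
                        animalLevel = "numeric", debrisLevel = "numeric",
                        curl = "numeric", staticAnimal = "logical",
                        seed = "integer"))

setValidity("SceneConfig", function(object) {
    if (length(object@imageSizePx) != 2L || any(object@imageSizePx < 16L))
        return("imageSizePx must be two integers >= 16")
    if (object@pixelScaleMm <= 0)
        return("pixelScaleMm must be positive")
    if (object@nFrames < 3L)
        return("need at least 3 frames")
    if (!(object@animalLengthMm > object@animalWidthMm &&
          object@animalWidthMm > 0))
        return("need animalLengthMm > animalWidthMm > 0")
    if (length(object@debrisAreaRangeMm2) != 2L ||
        any(object@debrisAreaRangeMm2 <= 0) ||
        diff(object@debrisAreaRangeMm2) < 0)
        return("debrisAreaRangeMm2 must be an increasing positive pair")
    if (object@noiseSd < 0)
        return("noiseSd must be >= 0")
    if (length(object@seed) != 1L || is.na(object@seed))
        return("an explicit integer seed is mandatory")
    if (any(object@curl < 0 | object@curl >= 1))
        return("curl values must lie in [0, 1)")
    TRUE
})

#' GroundTruth: what the synthetic scene actually contains
#'
#' @slot trueLengthMm the rendered capsule's end-to-end extent in mm.
#' @slot poses data.frame (frame, row, col, angleDeg, curl): per-frame
#'   animal pose, pixel coordinates of the body centroid axis midpoint.
#' @slot debris data.frame (row, col, radiusPx, areaMm2) of static specks.
#' @name GroundTruth-class
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
         representation(trueLengthMm = "numeric", poses = "data.frame",
                        debris = "data.frame"))

setValidity("GroundTruth", function(object) {
    if (object@trueLengthMm <= 0)
        return("trueLengthMm must be positive")
    TRUE
})
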