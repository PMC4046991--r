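#' Constructors for measurement-stage value objects
#'
#' \code{MeasurementSet} collects the per-patch M values (fitted-ellipse
#' major axes, mm) of one individual; \code{FilterConfig} holds the
#' critical ratio; \code{CalibrationModel} the affine M-to-length map.
#'
#' @param individualId opaque label for the animal.
#' @param records data.frame with columns frameIndex and majorMm (or a bare
#'   numeric vector of M values, in which case frame indices are NA).
#' @return the corresponding S4 object.
#' @export
MeasurementSet <- function(individualId = "individual", records) {
    if (is.numeric(records))
        records <- data.frame(frameIndex = rep(NA_integer_,
                                               length(records)),
                              majorMm = as.numeric(records))
    records <- as.data.frame(records)[, c("frameIndex", "majorMm")]
    rownames(records) <- NULL
    new("MeasurementSet", individualId = as.character(individualId),
        records = records)
}

#' @rdname MeasurementSet
#' @param criticalRatio fraction of the maximum M below which records are
#'   discarded; default 0.939 (the published instrument value).
#' @export
FilterConfig <- function(criticalRatio = 0.939) {
    new("FilterConfig", criticalRatio = criticalRatio)
}

#' @rdname MeasurementSet
#' @param slope,intercept affine calibration coefficients; defaults 0.930
#'   and -0.070 mm (the published instrument constants).
#' @param rSquared optional fit diagnostic.
#' @export
CalibrationModel <- function(slope = 0.930, intercept = -0.070,
                             rSquared = NA_real_) {
    new("CalibrationModel", slope = slope, intercept = intercept,
        rSquared = as.numeric(rSquared))
}

#' Critical-ratio filtering of M values
#'
#' Discards every M record smaller than criticalRatio times the
#' individual's largest M. Small records arise when the animal moves too
#' little (its patch splits) or curls into an irregular posture; since the
#' animals rarely stretch, the larger M values are the more precise ones.
#' Records exactly at the cutoff are retained ("less than" the cutoff is
#' omitted), so the maximum itself always survives and the result is never
#' empty.
#'
#' @param ms a non-empty \linkS4class{MeasurementSet}.
#' @param cfg a \linkS4class{FilterConfig}; default ratio 0.939.
#' @return a \linkS4class{MeasurementSet} with only the surviving records.
#' @examples
#' ms <- MeasurementSet("a", c(1.00, 0.95, 0.90))
#' measurements(filterMValues(ms))$majorMm  # 1.00 and 0.95
#' @export
filterMValues <- function(ms, cfg = FilterConfig()) {
    stopifnot(is(ms, "MeasurementSet"), is(cfg, "FilterConfig"))
    r <- measurements(ms)
    if (nrow(r) == 0L)
        stop(inputError("cannot filter an empty MeasurementSet"))
    keep <- r$majorMm >= cfg@criticalRatio * max(r$majorMm)
    MeasurementSet(individualId(ms), r[keep, , drop = FALSE])
}

#' Apply the affine length calibration to M values
#'
#' body length = slope * M + intercept. A non-positive result signals a
#' calibration that is non-physical for this input and raises an error
#' rather than clamping.
#'
#' @param majorMm positive M value(s) in mm.
#' @param model a \linkS4class{CalibrationModel}.
#' @return calibrated body length(s) in mm.
#' @examples
#' applyCalibration(1.0, CalibrationModel())  # 0.86
#' @export
applyCalibration <- function(majorMm, model = CalibrationModel()) {
    stopifnot(is(model, "CalibrationModel"))
    if (any(!is.finite(majorMm) | majorMm <= 0))
        stop(inputError("majorMm must be positive"))
    out <- model@slope * majorMm + model@intercept
    if (any(out <= 0))
        stop(inputError(sprintf(
            "calibration %.4g*M%+.4g yields a non-positive length for M = %.4g mm",
            model@slope, model@intercept, majorMm[which(out <= 0)[1L]])))
    out
}

#' One body length per individual: filter, calibrate, average
#'
#' The estimate is the arithmetic mean of the calibrated M values that
#' survive the critical-ratio filter. Because the calibration is affine,
#' this equals slope * mean(kept M) + intercept.
#'
#' @param ms a non-empty \linkS4class{MeasurementSet}.
#' @param cfg a \linkS4class{FilterConfig}.
#' @param model a \linkS4class{CalibrationModel}.
#' @return a \linkS4class{BodyLengthEstimate}.
#' @examples
#' est <- estimateBodyLength(MeasurementSet("a", c(1.00, 0.95, 0.90)))
#' bodyLength(est)  # mean(0.860, 0.8135) = 0.83675
#' @export
estimateBodyLength <- function(ms, cfg = FilterConfig(),
                               model = CalibrationModel()) {
    stopifnot(is(ms, "MeasurementSet"))
    nRaw <- nrow(measurements(ms))
    if (nRaw == 0L)
        stop(noMotionError(sprintf(
            "no M records for '%s': the animal produced no motion patches",
            individualId(ms))))
    kept <- filterMValues(ms, cfg)
    keptRec <- measurements(kept)
    new("BodyLengthEstimate",
        individualId = individualId(ms),
        lengthMm = mean(applyCalibration(keptRec$majorMm, model)),
        nRaw = as.integer(nRaw), nKept = nrow(keptRec),
        keptRecords = keptRec)
}

#' Full pipeline on one frame sequence
#'
#' \code{analyzeSequence} runs secondary differencing, thresholding,
#' particle extraction with the area gate, pools the particles of all
#' secondary difference images into one MeasurementSet, and applies the
#' filter-calibrate-average estimator. Split patches from insufficient
#' motion simply contribute smaller M rows that the critical-ratio filter
#' then removes. \code{measureSequence} returns just the estimate.
#'
#' @param seq a \linkS4class{FrameSequence} (>= 3 frames), one animal.
#' @param individualId label carried into the outputs.
#' @param cfg a \linkS4class{FilterConfig}.
#' @param gate an \linkS4class{AreaGate}.
#' @param model a \linkS4class{CalibrationModel}.
#' @param threshold "otsu" or "fixed" (see \code{\link{thresholdMask}}).
#' @param noiseFloor minimum Otsu cutoff.
#' @param fixedLevel cutoff when \code{threshold = "fixed"}.
#' @return \code{analyzeSequence}: list with \code{particles} (one row per
#'   patch, including keptFlag and calibratedLengthMm, NA where the
#'   calibration would be non-positive) and \code{estimate} (a
#'   \linkS4class{BodyLengthEstimate}). \code{measureSequence}: the
#'   estimate alone.
#' @export
analyzeSequence <- function(seq, individualId = "individual",
                            cfg = FilterConfig(), gate = AreaGate(),
                            model = CalibrationModel(),
                            threshold = c("otsu", "fixed"),
                            noiseFloor = 0.05, fixedLevel = NULL) {
    stopifnot(is(seq, "FrameSequence"))
    threshold <- match.arg(threshold)
    diffs <- secondaryDifferences(seq)
    parts <- lapply(diffs, function(d) {
        m <- thresholdMask(d, noiseFloor = noiseFloor, method = threshold,
                           fixedLevel = fixedLevel)
        findParticles(m, pixelScale(seq), gate, frameIndex = diffIndex(d))
    })
    all <- do.call(rbind, parts)
    rownames(all) <- NULL
    if (nrow(all) == 0L)
        stop(noMotionError(sprintf(
            "no particles found in any secondary difference image of '%s' (no-motion condition)",
            individualId)))
    ms <- MeasurementSet(individualId,
                         all[, c("frameIndex", "majorMm")])
    est <- estimateBodyLength(ms, cfg, model)
    all$keptFlag <- all$majorMm >= criticalRatio(cfg) * max(all$majorMm)
    cal <- model@slope * all$majorMm + model@intercept
    all$calibratedLengthMm <- ifelse(cal > 0, cal, NA_real_)
    list(particles = all, estimate = est)
}

#' @rdname analyzeSequence
#' @param ... passed on to \code{analyzeSequence}.
#' @export
measureSequence <- function(seq, ...) {
    analyzeSequence(seq, ...)$estimate
}
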