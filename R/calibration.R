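#' Fit the M-to-length calibration by least squares
#'
#' Ordinary least squares of the operator-measured body length on the
#' fitted-ellipse major axis M from the corresponding secondary difference
#' image. Because the ellipse takes protruding appendages into account, M
#' systematically exceeds the head-to-abdomen length, which a slope below
#' one and a negative intercept correct; the published instrument equation
#' (body length = 0.930 M - 0.070, R^2 = 0.98) was obtained exactly this
#' way from 50 manually measured animals.
#'
#' @param pairs data.frame with columns manualLengthMm and majorMm, one row
#'   per animal; at least 3 rows, M values not all identical.
#' @return a \linkS4class{CalibrationModel} with rSquared filled in.
#' @examples
#' p <- data.frame(majorMm = 1:5 / 2)
#' p$manualLengthMm <- 0.9 * p$majorMm - 0.05
#' fitCalibration(p)
#' @export
fitCalibration <- function(pairs) {
    pairs <- as.data.frame(pairs)
    need <- c("manualLengthMm", "majorMm")
    if (!all(need %in% names(pairs)))
        stop(inputError("pairs needs columns manualLengthMm and majorMm"))
    if (nrow(pairs) < 3L)
        stop(inputError("need at least 3 calibration pairs"))
    if (any(pairs$manualLengthMm <= 0) || any(pairs$majorMm <= 0))
        stop(inputError("lengths and M values must be positive"))
    if (stats::var(pairs$majorMm) < .Machine$double.eps)
        stop(inputError("degenerate design: all M values identical"))
    fit <- stats::lm(manualLengthMm ~ majorMm, data = pairs)
    # summary.lm warns on noiseless input; a perfect fit is fine here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    CalibrationModel(slope = unname(stats::coef(fit)[2L]),
                     intercept = unname(stats::coef(fit)[1L]),
                     rSquared = r2)
}

#' Derive the critical ratio from posture annotations
#'
#' For each individual, the critical value is the lowest M among frames
#' annotated as showing a regular (straight, measurable) posture; dividing
#' it by the individual's highest M over all its frames gives that
#' individual's critical ratio. The instrument threshold is the mean ratio
#' across individuals (the published study obtained 0.939 +- 0.027 from 50
#' animals). Individuals with no regular frame are skipped with a warning
#' and listed in the result.
#'
#' @param annotations data.frame with columns individualId, frameIndex,
#'   majorMm, regular (logical).
#' @return list with meanRatio, sdRatio (sample SD, n-1 denominator; NA for
#'   a single individual), perIndividual (data.frame individualId, ratio,
#'   nRegular, nTotal) and skipped (ids without any regular frame).
#' @examples
#' ann <- data.frame(individualId = "a", frameIndex = 2:4,
#'                   majorMm = c(1.00, 0.97, 0.90),
#'                   regular = c(TRUE, TRUE, FALSE))
#' determineCriticalRatio(ann)$meanRatio  # 0.97
#' @export
determineCriticalRatio <- function(annotations) {
    a <- as.data.frame(annotations)
    need <- c("individualId", "frameIndex", "majorMm", "regular")
    if (!all(need %in% names(a)))
        stop(inputError(paste("annotations needs columns",
                              paste(need, collapse = ", "))))
    if (any(a$majorMm <= 0))
        stop(inputError("all majorMm must be positive"))
    a$regular <- as.logical(a$regular)
    ids <- unique(a$individualId)
    per <- lapply(ids, function(id) {
        sub <- a[a$individualId == id, , drop = FALSE]
        if (!any(sub$regular)) return(NULL)
        data.frame(individualId = id,
                   ratio = min(sub$majorMm[sub$regular]) / max(sub$majorMm),
                   nRegular = sum(sub$regular), nTotal = nrow(sub))
    })
    skipped <- ids[vapply(per, is.null, logical(1L))]
    per <- do.call(rbind, per)
    if (is.null(per) || nrow(per) == 0L)
        stop(inputError("no individual has any regular frame"))
    if (length(skipped) > 0L)
        warning(sprintf("%d individual(s) without a regular frame skipped: %s",
                        length(skipped), paste(skipped, collapse = ", ")))
    rownames(per) <- NULL
    list(meanRatio = mean(per$ratio),
         sdRatio = if (nrow(per) > 1L) stats::sd(per$ratio) else NA_real_,
         perIndividual = per,
         skipped = as.character(skipped))
}

# ---- CSV readers (headers required, UTF-8, dot decimal separator) ----

#' Read calibration inputs from CSV
#'
#' \code{readCalibrationPairs} expects columns individual_id,
#' manual_length_mm, major_mm; \code{readRegularityAnnotations} expects
#' individual_id, frame_index, major_mm, regular. Snake_case headers are
#' mapped onto the camelCase columns the fitting functions use.
#'
#' @param path CSV file path.
#' @return a data.frame ready for \code{\link{fitCalibration}} or
#'   \code{\link{determineCriticalRatio}}.
#' @export
readCalibrationPairs <- function(path) {
    d <- readCsvChecked(path, c("individual_id", "manual_length_mm",
                                "major_mm"))
    data.frame(individualId = as.character(d$individual_id),
               manualLengthMm = as.numeric(d$manual_length_mm),
               majorMm = as.numeric(d$major_mm))
}

#' @rdname readCalibrationPairs
#' @export
readRegularityAnnotations <- function(path) {
    d <- readCsvChecked(path, c("individual_id", "frame_index", "major_mm",
                                "regular"))
    data.frame(individualId = as.character(d$individual_id),
               frameIndex = as.integer(d$frame_index),
               majorMm = as.numeric(d$major_mm),
               regular = as.logical(toupper(as.character(d$regular)) %in%
                                    c("TRUE", "T", "1", "YES")))
}

readCsvChecked <- function(path, required) {
    if (!file.exists(path))
        stop(inputError(sprintf("file not found: %s", path)))
    d <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
    missing <- setdiff(required, names(d))
    if (length(missing) > 0L)
        stop(inputError(sprintf("%s lacks required column(s): %s", path,
                                paste(missing, collapse = ", "))))
    d
}
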