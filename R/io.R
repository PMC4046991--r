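#' Read a directory of frames as a FrameSequence
#'
#' Files matching \code{pattern} are ordered by the natural numeric order
#' of their names (img_2 before img_10), decoded (PNG/TIFF/JPEG),
#' converted to grayscale and normalized to [0, 1]. All frames must share
#' one size; fewer than 3 matching files is an error.
#'
#' @param path directory containing the frames.
#' @param pattern file-name regular expression; default matches
#'   png/tif/tiff/jpg/jpeg (case-insensitive).
#' @param pixelScaleMm mm per pixel edge; default 0.0246.
#' @param intervalS seconds between frames; default 3.
#' @return a \linkS4class{FrameSequence}.
#' @export
readSequence <- function(path, pattern = "\\.(png|tiff?|jpe?g)$",
                         pixelScaleMm = 0.0246, intervalS = 3) {
    if (!dir.exists(path))
        stop(inputError(sprintf("directory not found: %s", path)))
    files <- list.files(path, pattern = pattern, ignore.case = TRUE)
    if (length(files) < 3L)
        stop(inputError(sprintf(
            "need at least 3 frames; %d file(s) in %s match '%s'",
            length(files), path, pattern)))
    files <- files[naturalOrder(files)]
    frames <- lapply(files, function(fn) {
        f <- file.path(path, fn)
        img <- tryCatch(EBImage::readImage(f), error = function(e)
            stop(inputError(sprintf("cannot decode %s: %s", f,
                                    conditionMessage(e)))))
        a <- EBImage::imageData(img)
        # EBImage stores images x-major: dim 1 is the column axis
        a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
        if (length(dim(a)) == 3L && dim(a)[3L] == 4L)
            a <- a[, , 1:3, drop = FALSE]    # drop alpha
        pmin(pmax(toGrayscale(a), 0), 1)
    })
    d <- dim(frames[[1L]])
    bad <- which(!vapply(frames, function(x) identical(dim(x), d),
                         logical(1L)))
    if (length(bad) > 0L)
        stop(inputError(sprintf(
            "frames have mixed dimensions (e.g. %s is %s, %s is %s)",
            files[1L], paste(d, collapse = "x"), files[bad[1L]],
            paste(dim(frames[[bad[1L]]]), collapse = "x"))))
    FrameSequence(frames, pixelScaleMm = pixelScaleMm,
                  intervalS = intervalS)
}

#' Write a FrameSequence as numbered PNG files
#'
#' @param seq a \linkS4class{FrameSequence}.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix; frames become prefix_001.png, ...
#' @return the file paths, invisibly.
#' @export
writeFrames <- function(seq, dir, prefix = "frame") {
    stopifnot(is(seq, "FrameSequence"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    f <- frames(seq)
    paths <- file.path(dir, sprintf("%s_%03d.png", prefix, seq_along(f)))
    for (i in seq_along(f))
        EBImage::writeImage(EBImage::Image(t(f[[i]])), paths[i])
    invisible(paths)
}

#' Export particle measurements and per-individual summaries
#'
#' Writes a tab-separated UTF-8 table with a header row, one row per patch
#' ("each row corresponding to one patch"), mm values with 4 decimal
#' places, in deterministic (individual, frame, label) order. When
#' \code{summaryFile} is given, a companion table with one calibrated
#' length per individual is written next to it.
#'
#' @param analyses the result of \code{\link{analyzeSequence}}, or a list
#'   of such results (one per individual).
#' @param file path of the per-patch TSV.
#' @param summaryFile optional path of the per-individual summary TSV.
#' @return \code{file}, invisibly.
#' @export
writeResults <- function(analyses, file, summaryFile = NULL) {
    if (!is.null(analyses$particles))
        analyses <- list(analyses)
    fmt <- function(x) sprintf("%.4f", x)
    pr <- do.call(rbind, lapply(analyses, function(a) {
        p <- a$particles
        est <- a$estimate
        if (is.null(p) || nrow(p) == 0L) return(NULL)
        data.frame(individual_id = individualId(est),
                   frame_index = p$frameIndex,
                   label = p$label,
                   pixel_count = p$pixelCount,
                   area_mm2 = fmt(p$areaMm2),
                   major_mm = fmt(p$majorMm),
                   minor_mm = fmt(p$minorMm),
                   angle_deg = fmt(p$angleDeg),
                   kept_flag = p$keptFlag,
                   calibrated_length_mm = ifelse(
                       is.na(p$calibratedLengthMm), "NA",
                       fmt(p$calibratedLengthMm)))
    }))
    if (is.null(pr))
        pr <- data.frame(individual_id = character(0),
                         frame_index = integer(0), label = integer(0),
                         pixel_count = integer(0), area_mm2 = character(0),
                         major_mm = character(0), minor_mm = character(0),
                         angle_deg = character(0), kept_flag = logical(0),
                         calibrated_length_mm = character(0))
    pr <- pr[order(pr$individual_id, pr$frame_index, pr$label), ,
             drop = FALSE]
    utils::write.table(pr, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    if (!is.null(summaryFile)) {
        sm <- do.call(rbind, lapply(analyses, function(a) {
            est <- a$estimate
            if (is.null(est)) return(NULL)
            data.frame(individual_id = individualId(est),
                       length_mm = fmt(bodyLength(est)),
                       n_raw = nRaw(est), n_kept = nKept(est))
        }))
        if (is.null(sm))
            sm <- data.frame(individual_id = character(0),
                             length_mm = character(0), n_raw = integer(0),
                             n_kept = integer(0))
        sm <- sm[order(sm$individual_id), , drop = FALSE]
        utils::write.table(sm, summaryFile, sep = "\t", quote = FALSE,
                           row.names = FALSE, fileEncoding = "UTF-8")
    }
    invisible(file)
}
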