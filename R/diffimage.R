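#' Construct a FrameSequence
#'
#' Bundles an ordered list of frames with the physical pixel scale. Color
#' frames (3-channel arrays, channels last) are converted to grayscale;
#' 2-D matrices are taken as-is.
#'
#' @param frames list of numeric matrices or 3-channel arrays with
#'   intensities in [0, 1], in capture order.
#' @param pixelScaleMm mm per pixel edge; the instrument default is 0.0246
#'   (24.6 micrometers).
#' @param intervalS seconds between consecutive frames (metadata; the
#'   capture protocol default is 3 s).
#' @return a \linkS4class{FrameSequence}.
#' @examples
#' fs <- FrameSequence(replicate(3, matrix(0.5, 8, 8), simplify = FALSE))
#' nFrames(fs)
#' @export
FrameSequence <- function(frames, pixelScaleMm = 0.0246, intervalS = 3) {
    if (!is.list(frames))
        stop(inputError("frames must be a list of rasters"))
    new("FrameSequence", frames = lapply(frames, toGrayscale),
        pixelScaleMm = pixelScaleMm, intervalS = intervalS)
}

#' Convert a raster to single-channel grayscale
#'
#' The analysis is single-channel even though the camera is a color CCD.
#' 3-channel input is combined with Rec. 709 luminance weights
#' (0.2126 R + 0.7152 G + 0.0722 B); 2-D input is returned unchanged
#' (idempotent).
#'
#' @param raster a numeric matrix, or a 3-D array with the channel as the
#'   last dimension (1 or 3 channels).
#' @return a numeric matrix with values in [0, 1].
#' @examples
#' toGrayscale(array(1, dim = c(4, 4, 3)))[1, 1]  # 1 (white)
#' @export
toGrayscale <- function(raster) {
    if (is.matrix(raster) && is.numeric(raster))
        return(raster)
    if (!(is.array(raster) && length(dim(raster)) == 3L))
        stop(inputError("raster must be a matrix or a 3-D channels-last array"))
    nch <- dim(raster)[3L]
    if (nch == 1L)
        return(raster[, , 1L])
    if (nch != 3L)
        stop(inputError(sprintf("unsupported channel count: %d", nch)))
    0.2126 * raster[, , 1L] + 0.7152 * raster[, , 2L] + 0.0722 * raster[, , 3L]
}

#' Secondary difference images of a frame sequence
#'
#' For every interior frame t, computes the difference with the previous
#' frame and the difference with the next frame, and combines the two into
#' one secondary difference image: the pixelwise minimum of the absolute
#' differences. A pixel is bright only where frame t differs from both
#' neighbours, so the static background cancels exactly and the animal's
#' previous/next "ghost" positions are suppressed; what remains is the
#' animal's position in the central frame. A series of ten frames yields
#' eight secondary difference images.
#'
#' @param seq a \linkS4class{FrameSequence} with at least 3 frames.
#' @return list of \linkS4class{SecondaryDiff}, one per interior frame,
#'   in frame order (indices 2 .. n-1).
#' @examples
#' f <- replicate(10, matrix(runif(64), 8, 8), simplify = FALSE)
#' length(secondaryDifferences(FrameSequence(f)))  # 8
#' @export
secondaryDifferences <- function(seq) {
    stopifnot(is(seq, "FrameSequence"))
    n <- nFrames(seq)
    if (n < 3L)
        stop(inputError("secondary differences need at least 3 frames"))
    f <- frames(seq)
    lapply(2L:(n - 1L), function(t) {
        new("SecondaryDiff", index = t,
            raster = pmin(abs(f[[t]] - f[[t - 1L]]),
                          abs(f[[t]] - f[[t + 1L]])))
    })
}
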