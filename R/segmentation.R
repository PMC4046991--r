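#' Threshold a secondary difference image
#'
#' Turns difference magnitudes into a binary mask. With \code{method =
#' "otsu"} the cutoff is Otsu's criterion on the raster histogram, but never
#' below \code{noiseFloor}: sensor noise produces a large near-zero mode
#' that can capture the Otsu cutoff when the moving animal occupies only a
#' tiny fraction of the field, and the floor guards against that. With
#' \code{method = "fixed"} the supplied level is used verbatim, so users can
#' match any specific instrument setting. Pixels strictly above the cutoff
#' are foreground; an all-zero raster always yields an empty mask.
#'
#' @param diff a \linkS4class{SecondaryDiff}.
#' @param noiseFloor minimum admissible cutoff in [0, 1); default 0.05.
#' @param method "otsu" (default) or "fixed".
#' @param fixedLevel cutoff for \code{method = "fixed"}.
#' @return a \linkS4class{BinaryMask}.
#' @export
thresholdMask <- function(diff, noiseFloor = 0.05,
                          method = c("otsu", "fixed"), fixedLevel = NULL) {
    stopifnot(is(diff, "SecondaryDiff"))
    method <- match.arg(method)
    if (!(noiseFloor >= 0 && noiseFloor < 1))
        stop(inputError("noiseFloor must lie in [0, 1)"))
    r <- diff@raster
    if (method == "fixed") {
        if (is.null(fixedLevel))
            stop(inputError("method = \"fixed\" requires fixedLevel"))
        cutoff <- fixedLevel
    } else {
        rng <- range(r)
        cutoff <- if (rng[2L] - rng[1L] < .Machine$double.eps) {
            # constant raster: nothing to separate
            max(noiseFloor, rng[2L])
        } else {
            max(noiseFloor,
                EBImage::otsu(EBImage::Image(r), range = c(0, 1),
                              levels = 256L))
        }
    }
    new("BinaryMask", mask = r > cutoff, thresholdUsed = cutoff)
}

# 8-connected component labeling of a logical matrix. Returns NULL for an
# empty mask, else a list with per-foreground-pixel row, col and label.
# Labels are assigned in row-major order of each component's first pixel,
# making them a pure function of the mask.
labelComponents <- function(mask) {
    idx <- which(mask)
    k <- length(idx)
    if (k == 0L) return(NULL)
    nr <- nrow(mask)
    rr <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    # each unordered neighbour pair is generated once via 4 backward offsets
    offs <- list(c(-1L, 0L), c(0L, -1L), c(-1L, -1L), c(1L, -1L))
    edges <- vector("list", length(offs))
    pos <- seq_len(k)
    for (i in seq_along(offs)) {
        o <- offs[[i]]
        nrr <- rr + o[1L]; ncc <- cc + o[2L]
        valid <- nrr >= 1L & nrr <= nr & ncc >= 1L
        m <- match(idx[valid] + o[1L] + o[2L] * nr, idx)
        hit <- !is.na(m)
        edges[[i]] <- rbind(pos[valid][hit], m[hit])
    }
    edges <- do.call(cbind, edges)
    membership <- if (is.null(edges) || ncol(edges) == 0L) {
        seq_len(k)
    } else {
        g <- igraph::make_graph(as.vector(edges), n = k, directed = FALSE)
        igraph::components(g)$membership
    }
    # relabel by row-major first-pixel order
    ord <- order(rr, cc)
    firsts <- membership[ord][!duplicated(membership[ord])]
    rank <- integer(max(membership))
    rank[firsts] <- seq_along(firsts)
    list(row = rr, col = cc, label = rank[membership])
}

#' Fit a moment-based ellipse to a pixel patch
#'
#' The ellipse shares the patch's centroid; its orientation and axis ratio
#' come from the second central moments of the member pixels, and its
#' absolute size is fixed by matching the ellipse area to the patch pixel
#' area — the convention of the particle-analysis tool whose "Major"
#' parameter the length calibration is fitted against. The diagonal central
#' moments include the 1/12 pixel-as-unit-square term, so even collinear
#' patches have a positive minor axis, and a single pixel maps to the
#' area-matched disc (major = minor = 2/sqrt(pi)).
#'
#' @param memberPixels a 2-column matrix or data.frame of (row, col) pixel
#'   coordinates; at least one pixel.
#' @return named numeric: majorPx, minorPx (ellipse axes in pixels, major >=
#'   minor > 0) and angleDeg (major-axis orientation in degrees
#'   counter-clockwise from the row axis, in [0, 180)).
#' @examples
#' fitEllipse(cbind(1, 1:9))  # a horizontal 9-pixel line
#' @export
fitEllipse <- function(memberPixels) {
    p <- as.matrix(memberPixels)
    if (nrow(p) < 1L)
        stop(inputError("fitEllipse needs at least one pixel"))
    if (ncol(p) != 2L)
        stop(inputError("memberPixels must have two columns (row, col)"))
    n <- nrow(p)
    r <- p[, 1L]; cl <- p[, 2L]
    dr <- r - mean(r); dc <- cl - mean(cl)
    mrr <- sum(dr * dr) / n + 1 / 12
    mcc <- sum(dc * dc) / n + 1 / 12
    mrc <- sum(dr * dc) / n
    mid <- (mrr + mcc) / 2
    disc <- sqrt(((mcc - mrr) / 2)^2 + mrc * mrc)
    q <- sqrt((mid + disc) / (mid - disc))   # axis ratio >= 1
    ang <- (0.5 * atan2(-2 * mrc, mcc - mrr) * 180 / pi) %% 180
    c(majorPx = 2 * sqrt(n * q / pi),
      minorPx = 2 * sqrt(n / (q * pi)),
      angleDeg = ang)
}

#' Extract gated particles from a binary mask
#'
#' Connected components under 8-connectivity (diagonal contact keeps thin
#' appendages attached), converted to physical area from the pixel count,
#' and kept only when the area lies inside the gate (inclusive on both
#' ends). Components outside the gate are dropped silently but counted in
#' the \code{dropped} attribute of the result. Each surviving particle
#' carries its moment-fitted ellipse axes in mm; the major axis is the M
#' statistic the body-length calibration consumes.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param pixelScaleMm mm per pixel edge (> 0).
#' @param gate an \linkS4class{AreaGate}; default 0.01–10 mm^2.
#' @param frameIndex central-frame index to record on each particle
#'   (NA when the mask is analyzed outside a sequence).
#' @return data.frame with one row per particle: label, frameIndex,
#'   pixelCount, areaMm2, centroidRow, centroidCol, majorMm, minorMm,
#'   angleDeg; rows ordered by label (row-major first-pixel order).
#'   Attribute \code{dropped}: named counts of components below/above the
#'   gate.
#' @export
findParticles <- function(mask, pixelScaleMm, gate = AreaGate(),
                          frameIndex = NA_integer_) {
    stopifnot(is(mask, "BinaryMask"), is(gate, "AreaGate"))
    if (!(pixelScaleMm > 0))
        stop(inputError("pixelScaleMm must be positive"))
    empty <- data.frame(label = integer(0), frameIndex = integer(0),
                        pixelCount = integer(0), areaMm2 = numeric(0),
                        centroidRow = numeric(0), centroidCol = numeric(0),
                        majorMm = numeric(0), minorMm = numeric(0),
                        angleDeg = numeric(0))
    lab <- labelComponents(mask@mask)
    if (is.null(lab)) {
        attr(empty, "dropped") <- c(below = 0L, above = 0L)
        return(empty)
    }
    px2 <- pixelScaleMm^2
    counts <- tabulate(lab$label)
    areas <- counts * px2
    keep <- which(areas >= gate@minMm2 & areas <= gate@maxMm2)
    dropped <- c(below = sum(areas < gate@minMm2),
                 above = sum(areas > gate@maxMm2))
    if (length(keep) == 0L) {
        attr(empty, "dropped") <- dropped
        return(empty)
    }
    rows <- lapply(keep, function(l) {
        sel <- lab$label == l
        pix <- cbind(lab$row[sel], lab$col[sel])
        e <- fitEllipse(pix)
        data.frame(label = l, frameIndex = frameIndex,
                   pixelCount = counts[l], areaMm2 = areas[l],
                   centroidRow = mean(pix[, 1L]),
                   centroidCol = mean(pix[, 2L]),
                   majorMm = unname(e["majorPx"]) * pixelScaleMm,
                   minorMm = unname(e["minorPx"]) * pixelScaleMm,
                   angleDeg = unname(e["angleDeg"]))
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$label), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "dropped") <- dropped
    out
}

#' Area gate constructor
#'
#' @param minMm2,maxMm2 inclusive bounds in mm^2; defaults 0.01 and 10.
#' @return an \linkS4class{AreaGate}.
#' @export
AreaGate <- function(minMm2 = 0.01, maxMm2 = 10) {
    new("AreaGate", minMm2 = minMm2, maxMm2 = maxMm2)
}
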