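#' Scene configuration for the synthetic generator
#'
#' See \linkS4class{SceneConfig} for the meaning of every parameter. Only
#' the ground-truth body length and the seed are required; the remaining
#' defaults emulate the imaging protocol (1504 x 1940 px field at 0.0246
#' mm/px, ten frames 3 s apart, dark animal on bright backlight, a few
#' static debris specks, sensor noise sigma 0.01).
#'
#' @param animalLengthMm ground-truth end-to-end body length in mm.
#' @param seed integer RNG seed (mandatory).
#' @param imageSizePx,pixelScaleMm,nFrames,animalWidthMm,appendageLengthMm
#'   see \linkS4class{SceneConfig}.
#' @param stepPx,allowOverlap,nDebris,debrisAreaRangeMm2,noiseSd see
#'   \linkS4class{SceneConfig}.
#' @param backgroundLevel,animalLevel,debrisLevel,curl,staticAnimal see
#'   \linkS4class{SceneConfig}.
#' @return a \linkS4class{SceneConfig}.
#' @export
SceneConfig <- function(animalLengthMm, seed,
                        imageSizePx = c(1504L, 1940L),
                        pixelScaleMm = 0.0246, nFrames = 10L,
                        animalWidthMm = 0.25, appendageLengthMm = 0,
                        stepPx = NA_real_, allowOverlap = FALSE,
                        nDebris = 3L, debrisAreaRangeMm2 = c(0.001, 0.02),
                        noiseSd = 0.01, backgroundLevel = 0.9,
                        animalLevel = 0.15, debrisLevel = 0.4, curl = 0,
                        staticAnimal = FALSE) {
    if (missing(seed))
        stop(inputError("SceneConfig requires an explicit seed"))
    new("SceneConfig", imageSizePx = as.integer(imageSizePx),
        pixelScaleMm = pixelScaleMm, nFrames = as.integer(nFrames),
        animalLengthMm = animalLengthMm, animalWidthMm = animalWidthMm,
        appendageLengthMm = appendageLengthMm, stepPx = as.numeric(stepPx),
        allowOverlap = allowOverlap, nDebris = as.integer(nDebris),
        debrisAreaRangeMm2 = debrisAreaRangeMm2, noiseSd = noiseSd,
        backgroundLevel = backgroundLevel, animalLevel = animalLevel,
        debrisLevel = debrisLevel, curl = curl,
        staticAnimal = staticAnimal, seed = as.integer(seed))
}

#' Moment-ellipse major axis of an ideal capsule
#'
#' Closed-form major axis of the area-matched moment ellipse of a
#' continuous capsule (rectangle of length L - W capped by two half-discs
#' of diameter W). This is what the segmentation stage converges to for a
#' straight synthetic animal as pixels shrink, and it makes the
#' shape-dependent bias of the ellipse statistic explicit: the returned
#' value exceeds L for elongated capsules.
#'
#' @param lengthMm end-to-end capsule length L.
#' @param widthMm capsule width W (< L).
#' @return the ellipse major axis in mm.
#' @examples
#' capsuleMomentMajor(1.2, 0.25)
#' @export
capsuleMomentMajor <- function(lengthMm, widthMm) {
    stopifnot(all(lengthMm > widthMm), all(widthMm > 0))
    r <- widthMm / 2
    h <- (lengthMm - widthMm) / 2
    A <- 4 * h * r + pi * r^2
    Ixx <- 4 * r * h^3 / 3 + pi * r^4 / 4 + (8 / 3) * h * r^3 +
        h^2 * pi * r^2
    Iyy <- 4 * h * r^3 / 3 + pi * r^4 / 4
    q <- sqrt(Ixx / Iyy)
    2 * sqrt(A * q / pi)
}

# ---- internal rendering helpers ----

# centerline sample points of a (possibly curled) capsule body.
# center: (row, col); angleDeg: orientation CCW from the row axis (same
# convention as fitEllipse); lenPx: centerline length; curl: fraction of a
# half-turn subtended by the bending arc. Returns a k x 2 matrix (row, col)
# plus the end tangent as an attribute (unit vector at the head end).
centerlinePoints <- function(center, angleDeg, lenPx, curl, spacing = 0.4) {
    th <- angleDeg * pi / 180
    u <- c(-sin(th), cos(th))          # along the axis (row, col)
    v <- c(-cos(th), -sin(th))         # normal
    if (lenPx <= 0) {
        pts <- matrix(center, 1L, 2L)
        attr(pts, "endTangent") <- u
        return(pts)
    }
    s <- seq(-lenPx / 2, lenPx / 2, by = spacing)
    if (s[length(s)] < lenPx / 2) s <- c(s, lenPx / 2)
    if (curl <= 0) {
        pts <- cbind(center[1L] + s * u[1L], center[2L] + s * u[2L])
        attr(pts, "endTangent") <- u
        return(pts)
    }
    phi <- curl * pi                   # total turning angle
    R <- lenPx / phi
    x <- R * sin(s / R)
    y <- R * (1 - cos(s / R))
    pts <- cbind(center[1L] + x * u[1L] + y * v[1L],
                 center[2L] + x * u[2L] + y * v[2L])
    aEnd <- (lenPx / 2) / R
    attr(pts, "endTangent") <- cos(aEnd) * u + sin(aEnd) * v
    pts
}

# paint all pixels whose center lies within `radius` of the polyline `pts`
stampTube <- function(f, pts, radius, level) {
    nr <- nrow(f); nc <- ncol(f)
    r0 <- max(1L, floor(min(pts[, 1L]) - radius - 1))
    r1 <- min(nr, ceiling(max(pts[, 1L]) + radius + 1))
    c0 <- max(1L, floor(min(pts[, 2L]) - radius - 1))
    c1 <- min(nc, ceiling(max(pts[, 2L]) + radius + 1))
    if (r0 > r1 || c0 > c1) return(f)
    pr <- rep.int(r0:r1, times = c1 - c0 + 1L)
    pc <- rep(c0:c1, each = r1 - r0 + 1L)
    if (nrow(pts) == 2L || nrow(pts) == 1L ||
        isTRUE(attr(pts, "straight"))) {
        a <- pts[1L, ]; b <- pts[nrow(pts), ]
        vr <- b[1L] - a[1L]; vc <- b[2L] - a[2L]
        L2 <- vr * vr + vc * vc
        t <- if (L2 == 0) 0 else
            pmin(1, pmax(0, ((pr - a[1L]) * vr + (pc - a[2L]) * vc) / L2))
        d2 <- (pr - (a[1L] + t * vr))^2 + (pc - (a[2L] + t * vc))^2
    } else {
        d2 <- rep.int(Inf, length(pr))
        for (i in seq_len(nrow(pts)))
            d2 <- pmin(d2, (pr - pts[i, 1L])^2 + (pc - pts[i, 2L])^2)
    }
    sel <- d2 <= radius * radius
    f[cbind(pr[sel], pc[sel])] <- level
    f
}

# straight bodies get the exact two-point segment representation
bodyPolyline <- function(center, angleDeg, lenPx, curl) {
    if (curl <= 0) {
        pts <- centerlinePoints(center, angleDeg, lenPx, 0,
                                spacing = max(lenPx, 1))
        pts <- pts[c(1L, nrow(pts)), , drop = FALSE]
        attr(pts, "straight") <- TRUE
        th <- angleDeg * pi / 180
        attr(pts, "endTangent") <- c(-sin(th), cos(th))
        pts
    } else {
        centerlinePoints(center, angleDeg, lenPx, curl)
    }
}

#' Generate one synthetic capture scene with ground truth
#'
#' Renders a dark capsule-shaped animal on a bright backlit background at a
#' fresh pose in every frame, identical debris specks in all frames, and
#' i.i.d. Gaussian sensor noise per pixel per frame; intensities are
#' clipped to [0, 1]. With \code{allowOverlap = FALSE} each pose is kept
#' disjoint from the two preceding ones, so every secondary difference
#' image contains the whole animal exactly once. The capsule's rendered
#' end-to-end extent equals \code{animalLengthMm / pixelScaleMm} pixels;
#' for a curled body the contour length is preserved while the chord
#' shortens, which is what makes curled postures yield smaller M values.
#' Everything is driven by \code{seed}: the same config reproduces
#' bit-identical frames.
#'
#' @param cfg a \linkS4class{SceneConfig}.
#' @return list with \code{sequence} (a \linkS4class{FrameSequence}) and
#'   \code{truth} (a \linkS4class{GroundTruth}).
#' @examples
#' sc <- generateScene(SceneConfig(0.8, seed = 1, imageSizePx = c(160, 200),
#'                                 nFrames = 3, nDebris = 1))
#' sc$truth
#' @export
generateScene <- function(cfg) {
    stopifnot(is(cfg, "SceneConfig"))
    validObject(cfg)
    nr <- cfg@imageSizePx[1L]; nc <- cfg@imageSizePx[2L]
    scl <- cfg@pixelScaleMm
    n <- cfg@nFrames
    extentPx <- cfg@animalLengthMm / scl
    wPx <- cfg@animalWidthMm / scl
    apxPx <- cfg@appendageLengthMm / scl
    lenPx <- extentPx - wPx              # centerline length
    reach <- extentPx / 2 + apxPx
    margin <- reach + 2
    if (2 * margin >= min(nr, nc))
        stop(inputError("animal (plus margin) does not fit inside the image"))
    minSep <- 2 * reach + 2
    step <- cfg@stepPx
    if (is.na(step))
        step <- if (cfg@allowOverlap) max(extentPx / 2, 2) else minSep
    if (!cfg@allowOverlap && step < minSep)
        stop(inputError(sprintf(
            "stepPx = %.1f cannot keep successive poses disjoint (need >= %.1f) with allowOverlap = FALSE",
            step, minSep)))
    curls <- rep(cfg@curl, length.out = n)

    withSeed(cfg@seed, {
        # pose path: uniform start, fixed-magnitude random-direction steps
        centers <- matrix(NA_real_, n, 2L)
        centers[1L, ] <- c(stats::runif(1, margin, nr - margin),
                           stats::runif(1, margin, nc - margin))
        if (cfg@staticAnimal) {
            centers[] <- rep(centers[1L, ], each = n)
        } else {
            for (t in 2L:n) {
                placed <- FALSE
                for (try in seq_len(500L)) {
                    ang <- stats::runif(1, 0, 2 * pi)
                    cand <- centers[t - 1L, ] + step * c(sin(ang), cos(ang))
                    if (cand[1L] < margin || cand[1L] > nr - margin ||
                        cand[2L] < margin || cand[2L] > nc - margin)
                        next
                    if (!cfg@allowOverlap && t > 2L &&
                        sqrt(sum((cand - centers[t - 2L, ])^2)) < minSep)
                        next
                    centers[t, ] <- cand
                    placed <- TRUE
                    break
                }
                if (!placed)
                    stop(inputError(
                        "could not place a displacement path inside the image"))
            }
        }
        angles <- stats::runif(n, 0, 180)
        if (cfg@staticAnimal) angles[] <- angles[1L]

        # static debris, kept clear of every animal pose
        debris <- if (cfg@nDebris > 0L) {
            rows <- lapply(seq_len(cfg@nDebris), function(i) {
                aMm2 <- stats::runif(1, cfg@debrisAreaRangeMm2[1L],
                                     cfg@debrisAreaRangeMm2[2L])
                rd <- sqrt(aMm2 / pi) / scl
                for (try in seq_len(500L)) {
                    p <- c(stats::runif(1, rd + 1, nr - rd - 1),
                           stats::runif(1, rd + 1, nc - rd - 1))
                    dmin <- min(sqrt((p[1L] - centers[, 1L])^2 +
                                     (p[2L] - centers[, 2L])^2))
                    if (dmin > reach + rd + 2)
                        return(data.frame(row = p[1L], col = p[2L],
                                          radiusPx = rd, areaMm2 = aMm2))
                }
                stop(inputError("could not place debris clear of the animal"))
            })
            do.call(rbind, rows)
        } else {
            data.frame(row = numeric(0), col = numeric(0),
                       radiusPx = numeric(0), areaMm2 = numeric(0))
        }

        base <- matrix(cfg@backgroundLevel, nr, nc)
        for (i in seq_len(nrow(debris)))
            base <- stampTube(base,
                              matrix(unlist(debris[i, c("row", "col")]),
                                     1L, 2L),
                              debris$radiusPx[i], cfg@debrisLevel)

        frames <- vector("list", n)
        for (t in seq_len(n)) {
            f <- base
            body <- bodyPolyline(centers[t, ], angles[t], lenPx, curls[t])
            f <- stampTube(f, body, wPx / 2, cfg@animalLevel)
            if (apxPx > 0) {
                head <- body[nrow(body), ]
                tg <- attr(body, "endTangent")
                for (dev in c(-20, 20) * pi / 180) {
                    rot <- matrix(c(cos(dev), sin(dev),
                                    -sin(dev), cos(dev)), 2L, 2L)
                    dirv <- as.vector(rot %*% tg)
                    seg <- rbind(head, head + apxPx * dirv)
                    attr(seg, "straight") <- TRUE
                    f <- stampTube(f, seg, 1, cfg@animalLevel)
                }
            }
            if (cfg@noiseSd > 0)
                f <- f + matrix(stats::rnorm(nr * nc, 0, cfg@noiseSd),
                                nr, nc)
            frames[[t]] <- pmin(pmax(f, 0), 1)
        }

        list(sequence = FrameSequence(frames, pixelScaleMm = scl,
                                      intervalS = 3),
             truth = new("GroundTruth",
                         trueLengthMm = cfg@animalLengthMm,
                         poses = data.frame(frame = seq_len(n),
                                            row = centers[, 1L],
                                            col = centers[, 2L],
                                            angleDeg = angles,
                                            curl = curls),
                         debris = debris))
    })
}

#' Generate a cohort of independent synthetic individuals
#'
#' Draws \code{nIndividuals} ground-truth body lengths uniformly over
#' \code{lengthRangeMm} under \code{seed}, then renders each individual's
#' scene with sub-seed \code{seed + i} so cohort members are independent
#' yet reproducible. This emulates an accuracy study in which dozens of
#' animals of assorted sizes are each photographed once.
#'
#' A full-size ten-frame sequence is large, so \code{FUN} allows streaming:
#' when supplied, \code{FUN(sequence, truth)} is called per individual and
#' only its value is kept, letting a whole cohort be generated, measured
#' and discarded one animal at a time.
#'
#' @param nIndividuals cohort size (>= 2).
#' @param lengthRangeMm (min, max) true lengths in mm; default the species'
#'   juvenile-to-adult span 0.3–2.5 mm.
#' @param baseCfg a \linkS4class{SceneConfig} template; its
#'   \code{animalLengthMm} and \code{seed} are overridden per individual.
#' @param seed cohort-level integer seed.
#' @param FUN optional function(sequence, truth) applied per individual.
#' @return list of length \code{nIndividuals}: each element is
#'   \code{list(sequence, truth)}, or the value of \code{FUN}.
#' @export
generateCohort <- function(nIndividuals, lengthRangeMm = c(0.3, 2.5),
                           baseCfg = SceneConfig(1, seed = 0L), seed,
                           FUN = NULL) {
    if (nIndividuals < 2L)
        stop(inputError("a cohort needs at least 2 individuals"))
    if (length(lengthRangeMm) != 2L || any(lengthRangeMm <= 0) ||
        diff(lengthRangeMm) <= 0)
        stop(inputError("lengthRangeMm must be an increasing positive pair"))
    if (missing(seed))
        stop(inputError("generateCohort requires an explicit seed"))
    stopifnot(is(baseCfg, "SceneConfig"))
    lengths <- withSeed(seed, stats::runif(nIndividuals, lengthRangeMm[1L],
                                           lengthRangeMm[2L]))
    lapply(seq_len(nIndividuals), function(i) {
        cfg <- initialize(baseCfg, animalLengthMm = lengths[i],
                          seed = as.integer(seed + i))
        sc <- generateScene(cfg)
        if (is.null(FUN)) sc else FUN(sc$sequence, sc$truth)
    })
}
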