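mkDiff <- function(m) new("SecondaryDiff", index = 2L, raster = m)

test_that("thresholding: Otsu separates a two-level raster, floor dominates noise", {
    r <- matrix(0, 30, 30)
    r[10:20, 5:15] <- 0.8
    bm <- thresholdMask(mkDiff(r), noiseFloor = 0.05)
    expect_true(thresholdUsed(bm) > 0 && thresholdUsed(bm) < 0.8)
    # exhaustive Otsu criterion over the histogram agrees on the split
    to <- oracleOtsu(as.vector(r))
    expect_true(to > 0 && to < 0.8)
    expect_identical(maskRaster(bm), r > thresholdUsed(bm))
    expect_identical(unname(maskRaster(bm)), unname(r == 0.8))

    expect_equal(sum(maskRaster(thresholdMask(mkDiff(matrix(0, 5, 5))))), 0)

    lowNoise <- matrix(0.02, 6, 6)
    bm2 <- thresholdMask(mkDiff(lowNoise), noiseFloor = 0.05)
    expect_equal(sum(maskRaster(bm2)), 0)

    bm3 <- thresholdMask(mkDiff(r), method = "fixed", fixedLevel = 0.5)
    expect_equal(thresholdUsed(bm3), 0.5)
    expect_error(thresholdMask(mkDiff(r), method = "fixed"), "fixedLevel")
    expect_error(thresholdMask(mkDiff(r), noiseFloor = 1), "noiseFloor")
})

test_that("particles are gated by physical area and labeled deterministically", {
    scl <- 0.0246
    m <- matrix(FALSE, 60, 60)
    m[5:24, 5:24] <- TRUE                       # 400 px ~ 0.242 mm^2
    m[40, 40] <- TRUE                           # 1 px, far below the gate
    p <- findParticles(new("BinaryMask", mask = m, thresholdUsed = 0.5), scl)
    expect_equal(nrow(p), 1L)
    expect_equal(p$areaMm2, 400 * scl^2)        # arithmetic oracle
    expect_equal(p$pixelCount, 400L)
    expect_equal(attr(p, "dropped"), c(below = 1L, above = 0L))

    # diagonal contact merges under 8-connectivity
    m2 <- matrix(FALSE, 30, 30)
    m2[5:9, 5:9] <- TRUE
    m2[10:14, 10:14] <- TRUE
    p2 <- findParticles(new("BinaryMask", mask = m2, thresholdUsed = 0.5),
                        scl, AreaGate(1e-4, 10))
    expect_equal(nrow(p2), 1L)
    expect_equal(p2$pixelCount, 50L)

    # empty mask: empty particle table
    p3 <- findParticles(new("BinaryMask", mask = matrix(FALSE, 4, 4),
                            thresholdUsed = 0.5), scl)
    expect_equal(nrow(p3), 0L)

    # labels follow row-major first-pixel order, a pure function of the mask
    m4 <- matrix(FALSE, 40, 40)
    m4[20:23, 2:5] <- TRUE      # first pixel row 20
    m4[2:5, 30:33] <- TRUE      # first pixel row 2 -> label 1
    p4 <- findParticles(new("BinaryMask", mask = m4, thresholdUsed = 0.5),
                        scl, AreaGate(1e-4, 10))
    expect_equal(p4$label, c(1L, 2L))
    expect_lt(p4$centroidRow[1], p4$centroidRow[2])
})

test_that("moment ellipse matches rasterized discs and ellipses", {
    disc <- rasterDisc(20)
    e <- fitEllipse(disc)
    expect_equal(unname(e["majorPx"]), 40, tolerance = 0.02)
    expect_equal(unname(e["minorPx"]), 40, tolerance = 0.02)

    ell <- rasterEllipse(40, 10)
    e2 <- fitEllipse(ell)
    expect_equal(unname(e2["majorPx"]), 80, tolerance = 0.02)
    expect_equal(unname(e2["minorPx"]), 20, tolerance = 0.02)
    expect_lt(min(abs(c(e2["angleDeg"], e2["angleDeg"] - 180))), 2)

    e3 <- fitEllipse(rasterEllipse(40, 10, angleDeg = 30))
    expect_equal(unname(e3["majorPx"]), unname(e2["majorPx"]),
                 tolerance = 0.02)
    expect_equal(unname(e3["minorPx"]), unname(e2["minorPx"]),
                 tolerance = 0.02)
    expect_equal(unname(e3["angleDeg"]), 30, tolerance = 0.05)

    # single pixel: area-matched disc
    e4 <- fitEllipse(cbind(5, 7))
    expect_equal(unname(e4["majorPx"]), 2 / sqrt(pi))
    expect_equal(unname(e4["minorPx"]), 2 / sqrt(pi))

    expect_error(fitEllipse(matrix(numeric(0), 0, 2)), "at least one")
})

test_that("fitEllipse equals the naive double-loop moment oracle", {
    set.seed(99)
    shapes <- list(rasterDisc(6), rasterEllipse(12, 5, 72),
                   cbind(3, 1:15),                       # collinear line
                   cbind(sample(1:30, 40, TRUE), sample(1:30, 40, TRUE)))
    for (pix in shapes) {
        pix <- unique(pix)
        got <- fitEllipse(pix)
        want <- bruteEllipse(pix)
        expect_equal(unname(got["majorPx"]), unname(want["major"]),
                     tolerance = 1e-9)
        expect_equal(unname(got["minorPx"]), unname(want["minor"]),
                     tolerance = 1e-9)
        expect_gt(unname(got["minorPx"]), 0)
    }
})

test_that("major axis is rotation robust within 2 percent", {
    ref <- fitEllipse(rasterEllipse(25, 8, 0))["majorPx"]
    for (ang in seq(10, 170, by = 20)) {
        got <- fitEllipse(rasterEllipse(25, 8, ang))["majorPx"]
        expect_equal(unname(got), unname(ref), tolerance = 0.02)
    }
})

test_that("gate soundness: no returned particle lies outside the gate", {
    set.seed(5)
    gate <- AreaGate(0.01, 10)
    for (i in 1:8) {
        m <- matrix(runif(2500) < 0.3, 50, 50)
        p <- findParticles(new("BinaryMask", mask = m, thresholdUsed = 0.5),
                           0.0246, gate)
        if (nrow(p) > 0)
            expect_true(all(p$areaMm2 >= 0.01 & p$areaMm2 <= 10))
    }
})
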