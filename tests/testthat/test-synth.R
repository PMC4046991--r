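test_that("the generator is bit-reproducible for a given config", {
    cfg <- SceneConfig(0.8, seed = 5, imageSizePx = c(200, 260),
                       nFrames = 4)
    a <- generateScene(cfg)
    b <- generateScene(cfg)
    expect_identical(frames(a$sequence), frames(b$sequence))
    expect_identical(poses(a$truth), poses(b$truth))
})

test_that("a static noiseless scene produces all-zero secondary differences", {
    sc <- smallScene(0.8, seed = 9, rows = 200, cols = 260,
                     staticAnimal = TRUE, noiseSd = 0, nDebris = 5)
    for (d in secondaryDifferences(sc$sequence))
        expect_equal(max(diffRaster(d)), 0)
})

test_that("no debris pixel survives secondary differencing", {
    sc <- smallScene(0.9, seed = 10, rows = 260, cols = 320, noiseSd = 0,
                     nDebris = 4)
    db <- debris(sc$truth)
    expect_equal(nrow(db), 4L)
    for (d in secondaryDifferences(sc$sequence)) {
        r <- diffRaster(d)
        for (i in seq_len(nrow(db)))
            expect_equal(r[round(db$row[i]), round(db$col[i])], 0)
    }
})

test_that("rendered capsule extent equals the true length within one pixel", {
    for (L in c(0.5, 1.3, 2.2)) {
        sc <- generateScene(SceneConfig(L, seed = 33,
                                        imageSizePx = c(420, 520),
                                        nFrames = 3, noiseSd = 0,
                                        nDebris = 0))
        f <- frames(sc$sequence)[[1]]
        pose <- poses(sc$truth)[1, ]
        pix <- which(f < 0.5, arr.ind = TRUE)
        th <- pose$angleDeg * pi / 180
        proj <- -pix[, 1] * sin(th) + pix[, 2] * cos(th)
        extent <- max(proj) - min(proj) + 1
        expect_equal(extent, L / 0.0246, tolerance = 1 / (L / 0.0246))
    }
})

test_that("appendages push the raw M above the true body length", {
    plain <- smallScene(1.0, seed = 40, rows = 340, cols = 420,
                        noiseSd = 0, nDebris = 0)
    fuzzy <- smallScene(1.0, seed = 40, rows = 340, cols = 420,
                        noiseSd = 0, nDebris = 0, appendageLengthMm = 0.35)
    id <- CalibrationModel(1, 0)
    mPlain <- bodyLength(measureSequence(plain$sequence, model = id))
    mFuzzy <- bodyLength(measureSequence(fuzzy$sequence, model = id))
    expect_gt(mFuzzy, 1.0)        # ellipse overestimates with appendages
    expect_gt(mFuzzy, mPlain)
})

test_that("curled postures yield smaller M than straight ones", {
    straight <- smallScene(1.2, seed = 41, rows = 380, cols = 460,
                           noiseSd = 0, nDebris = 0)
    curled <- smallScene(1.2, seed = 41, rows = 380, cols = 460,
                         noiseSd = 0, nDebris = 0, curl = 0.6)
    id <- CalibrationModel(1, 0)
    expect_lt(bodyLength(measureSequence(curled$sequence, model = id)),
              bodyLength(measureSequence(straight$sequence, model = id)))
})

test_that("closed-form capsule major axis matches numerical integration", {
    for (L in c(0.5, 1.2, 2.4)) {
        expect_equal(capsuleMomentMajor(L, 0.25),
                     oracleCapsuleMajor(L, 0.25), tolerance = 1e-3)
    }
    expect_gt(capsuleMomentMajor(2.4, 0.25), 2.4)   # elongation bias
})

test_that("cohorts draw lengths in range with reproducible sub-seeds", {
    base <- SceneConfig(1, seed = 0, imageSizePx = c(220, 280),
                        nFrames = 3, nDebris = 0, noiseSd = 0)
    a <- generateCohort(4, c(0.4, 0.9), base, seed = 77)
    b <- generateCohort(4, c(0.4, 0.9), base, seed = 77)
    la <- vapply(a, function(x) trueLength(x$truth), numeric(1))
    lb <- vapply(b, function(x) trueLength(x$truth), numeric(1))
    expect_identical(la, lb)
    expect_true(all(la >= 0.4 & la <= 0.9))
    expect_gt(length(unique(la)), 1L)
    expect_identical(frames(a[[2]]$sequence), frames(b[[2]]$sequence))

    # streaming FUN sees the same individuals
    lc <- unlist(generateCohort(4, c(0.4, 0.9), base, seed = 77,
                                FUN = function(s, t) trueLength(t)))
    expect_identical(unname(lc), unname(la))

    expect_error(generateCohort(1, c(0.4, 0.9), base, seed = 1),
                 "at least 2")
    expect_error(generateCohort(3, c(0.9, 0.4), base, seed = 1),
                 "increasing")
})

test_that("impossible scenes are rejected", {
    expect_error(generateScene(SceneConfig(2.5, seed = 1,
                                           imageSizePx = c(60, 60))),
                 "fit")
    expect_error(SceneConfig(0.2, seed = 1, animalWidthMm = 0.25),
                 "animalLengthMm")
    expect_error(generateScene(SceneConfig(0.8, seed = 1,
                                           imageSizePx = c(300, 400),
                                           stepPx = 5,
                                           allowOverlap = FALSE)),
                 "disjoint")
})
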