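test_that("noiseless linear pairs are recovered exactly", {
    pairs <- data.frame(majorMm = seq(0.4, 2.4, by = 0.2))
    pairs$manualLengthMm <- 0.9 * pairs$majorMm - 0.05
    m <- fitCalibration(pairs)
    expect_equal(calSlope(m), 0.9)
    expect_equal(calIntercept(m), -0.05)
    expect_equal(rSquared(m), 1)
})

test_that("noisy simulation recovers the coefficients within 3 standard errors", {
    set.seed(2024)
    M <- runif(50, 0.4, 2.4)
    L <- 0.93 * M - 0.07 + rnorm(50, 0, 0.02)
    pairs <- data.frame(majorMm = M, manualLengthMm = L)
    m <- fitCalibration(pairs)
    sm <- summary(stats::lm(manualLengthMm ~ majorMm, pairs))$coefficients
    expect_lt(abs(calSlope(m) - 0.93), 3 * sm["majorMm", "Std. Error"])
    expect_lt(abs(calIntercept(m) + 0.07), 3 * sm["(Intercept)", "Std. Error"])
    expect_gt(rSquared(m), 0.95)
})

test_that("fitCalibration equals the closed-form OLS oracle", {
    set.seed(31)
    for (i in 1:5) {
        M <- runif(sample(5:40, 1), 0.3, 2.5)
        L <- pmax(0.05, 0.9 * M + rnorm(length(M), 0, 0.05))
        m <- fitCalibration(data.frame(majorMm = M, manualLengthMm = L))
        want <- oracleOls(M, L)
        expect_equal(calSlope(m), unname(want["slope"]), tolerance = 1e-10)
        expect_equal(calIntercept(m), unname(want["intercept"]),
                     tolerance = 1e-10)
        expect_equal(rSquared(m), unname(want["r2"]), tolerance = 1e-10)
    }
})

test_that("degenerate calibration designs are rejected", {
    two <- data.frame(majorMm = c(1, 2), manualLengthMm = c(0.9, 1.8))
    expect_error(fitCalibration(two), "at least 3")
    flat <- data.frame(majorMm = rep(1, 5),
                       manualLengthMm = seq(0.8, 1.2, by = 0.1))
    expect_error(fitCalibration(flat), "degenerate")
})

test_that("critical ratio follows the lowest-regular over highest-M rule", {
    ann <- data.frame(individualId = "a", frameIndex = 2:4,
                      majorMm = c(1.00, 0.97, 0.90),
                      regular = c(TRUE, TRUE, FALSE))
    cr <- determineCriticalRatio(ann)
    expect_equal(cr$meanRatio, 0.97)
    expect_true(is.na(cr$sdRatio))

    # two individuals: mean of per-individual ratios; sample SD
    ann2 <- rbind(
        data.frame(individualId = "a", frameIndex = 2:3,
                   majorMm = c(1.00, 0.95), regular = c(TRUE, TRUE)),
        data.frame(individualId = "b", frameIndex = 2:3,
                   majorMm = c(2.00, 1.86), regular = c(FALSE, TRUE)))
    cr2 <- determineCriticalRatio(ann2)
    expect_equal(cr2$meanRatio, mean(c(0.95, 0.93)))
    expect_equal(cr2$sdRatio, sd(c(0.95, 0.93)))

    # an individual whose only regular frame is its maximum: ratio 1
    ann3 <- data.frame(individualId = "c", frameIndex = 2:3,
                       majorMm = c(1.4, 1.1), regular = c(TRUE, FALSE))
    expect_equal(determineCriticalRatio(ann3)$perIndividual$ratio, 1)

    # order invariance
    perm <- ann2[sample(nrow(ann2)), ]
    expect_equal(determineCriticalRatio(perm)$meanRatio, cr2$meanRatio)

    # every ratio lies in (0, 1]
    set.seed(17)
    annR <- do.call(rbind, lapply(1:6, function(i)
        data.frame(individualId = paste0("i", i), frameIndex = 2:7,
                   majorMm = runif(6, 0.5, 2),
                   regular = sample(c(TRUE, FALSE), 6, TRUE,
                                    prob = c(0.7, 0.3)))))
    crR <- determineCriticalRatio(annR)
    expect_true(all(crR$perIndividual$ratio > 0 &
                    crR$perIndividual$ratio <= 1))
})

test_that("individuals without regular frames are skipped with a warning", {
    ann <- rbind(
        data.frame(individualId = "ok", frameIndex = 2L, majorMm = 1,
                   regular = TRUE),
        data.frame(individualId = "bad", frameIndex = 2L, majorMm = 1,
                   regular = FALSE))
    expect_warning(cr <- determineCriticalRatio(ann), "skipped")
    expect_equal(cr$skipped, "bad")
    expect_equal(nrow(cr$perIndividual), 1L)

    allBad <- data.frame(individualId = "x", frameIndex = 2:3,
                         majorMm = c(1, 1.1), regular = FALSE)
    expect_error(determineCriticalRatio(allBad), "regular")
})

test_that("CSV readers enforce headers and map onto internal columns", {
    pairsCsv <- tempfile(fileext = ".csv")
    writeLines(c("individual_id,manual_length_mm,major_mm",
                 "a,0.85,1.00", "b,1.20,1.38", "c,1.90,2.11"), pairsCsv)
    p <- readCalibrationPairs(pairsCsv)
    expect_equal(names(p), c("individualId", "manualLengthMm", "majorMm"))
    expect_equal(nrow(p), 3L)
    m <- fitCalibration(p)
    expect_gt(rSquared(m), 0.99)

    annCsv <- tempfile(fileext = ".csv")
    writeLines(c("individual_id,frame_index,major_mm,regular",
                 "a,2,1.00,TRUE", "a,3,0.97,true", "a,4,0.90,FALSE"),
               annCsv)
    a <- readRegularityAnnotations(annCsv)
    expect_equal(a$regular, c(TRUE, TRUE, FALSE))
    expect_equal(determineCriticalRatio(a)$meanRatio, 0.97)

    badCsv <- tempfile(fileext = ".csv")
    writeLines(c("id,len", "a,1"), badCsv)
    expect_error(readCalibrationPairs(badCsv), "required column")
    expect_error(readCalibrationPairs("/no/such/file.csv"), "not found")
})
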