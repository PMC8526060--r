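test_that("batch z-scoring standardizes every batch x measure block", {
    m <- MeasureMatrix(cbind(a = c(1, 2, 3, 11, 12, 13),
                             b = c(5, 5, 5, 1, 2, 3)),
                       batch = rep(c("b1", "b2"), each = 3),
                       assay = "arena", measure = c("a", "b"))
    expect_warning(z <- zscoreByBatch(m), "constant")
    v <- measureValues(z)
    expect_equal(v[1:3, 1], c(-1, 0, 1), ignore_attr = TRUE)  # sample SD of 1,2,3 is 1
    expect_equal(v[4:6, 1], c(-1, 0, 1), ignore_attr = TRUE)
    expect_equal(v[1:3, 2], c(0, 0, 0), ignore_attr = TRUE)   # constant block -> 0
    for (b in c("b1", "b2")) {
        rows <- batchLabels(z) == b
        expect_equal(mean(v[rows, 1]), 0)
        expect_equal(sd(v[rows, 1]), 1)
    }
})

test_that("z-scoring ignores missing entries and is idempotent", {
    set.seed(5)
    vals <- matrix(rnorm(40, mean = 10, sd = 3), 10, 4)
    vals[sample(40, 8)] <- NA
    vals[, 4] <- NA                       # all-missing measure
    m <- MeasureMatrix(vals, batch = rep(c("x", "y"), each = 5))
    z1 <- zscoreByMeasure(m)
    v1 <- measureValues(z1)
    expect_identical(unname(is.na(v1)), is.na(vals))
    for (j in 1:3) {
        expect_equal(mean(v1[, j], na.rm = TRUE), 0)
        expect_equal(sd(v1[, j], na.rm = TRUE), 1)
    }
    z2 <- zscoreByMeasure(z1)
    expect_equal(measureValues(z2), v1, tolerance = 1e-12)

    expect_equal(measureValues(zscoreByMeasure(
        MeasureMatrix(cbind(c(0, 10)))))[, 1],
        c(-1, 1) / sqrt(2), ignore_attr = TRUE)
})

test_that("merging matches measures by assay/measure, ignoring day except circadian", {
    a <- MeasureMatrix(matrix(rnorm(20), 10, 2),
                       batch = "d1",
                       assay = c("olfaction", "circadian"),
                       measure = c("odorOccupancy", "meanSpeed"),
                       day = c(7L, 1L))
    b <- MeasureMatrix(matrix(rnorm(20), 10, 2),
                       batch = "d2",
                       assay = c("olfaction", "circadian"),
                       measure = c("odorOccupancy", "meanSpeed"),
                       day = c(8L, 2L))
    suppressWarnings(merged <- matchAndConcatenate(zscoreByBatch(a),
                                                   zscoreByBatch(b)))
    keys <- measureKeys(merged)
    # odorOccupancy from day 7 and day 8 collapse into one column...
    expect_length(grep("olfaction.odorOccupancy", keys), 1)
    expect_false(anyNA(measureValues(merged)[, grep("odorOccupancy", keys)]))
    # ...while circadian meanSpeed day 1 and day 2 stay separate, each
    # half-missing
    circ <- grep("circadian.meanSpeed", keys)
    expect_length(circ, 2)
    for (j in circ)
        expect_equal(sum(is.na(measureValues(merged)[, j])), 10)
    rep <- S4Vectors::metadata(merged)$mergeReport
    expect_equal(rep$matchedKeys, "olfaction.odorOccupancy")
    expect_equal(rep$insertedMissing, 20)
})

test_that("merging is self-consistent and order-insensitive", {
    a <- makeBlockMatrix(n = 30, seed = 81)
    az <- zscoreByBatch(a)
    dbl <- matchAndConcatenate(az, az)
    expect_equal(nIndividuals(dbl), 60)
    expect_equal(nMeasures(dbl), nMeasures(a))
    expect_false(anyNA(measureValues(dbl)))

    bv <- matrix(rnorm(30 * 3), 30, 3,
                 dimnames = list(sprintf("flyB_%02d", 1:30), NULL))
    b <- MeasureMatrix(bv, batch = "other",
                       assay = "ymaze", measure = c("m1", "m2", "m3"))
    ab <- matchAndConcatenate(az, zscoreByBatch(b))
    ba <- matchAndConcatenate(zscoreByBatch(b), az)
    keys <- measureKeys(ab)
    vab <- measureValues(ab)[order(individualIds(ab)), keys]
    vba <- measureValues(ba)[order(individualIds(ba)), keys]
    expect_equal(vab, vba, tolerance = 1e-12)
})

test_that("merging rejects duplicate measure keys", {
    a <- MeasureMatrix(matrix(rnorm(20), 10, 2), assay = "ymaze",
                       measure = c("turns", "turns"))
    b <- MeasureMatrix(matrix(rnorm(10), 10, 1), assay = "ymaze",
                       measure = "bias")
    expect_error(matchAndConcatenate(a, b), "duplicate")
})

test_that("assembly is affine per cell: no values invented", {
    set.seed(9)
    vals <- matrix(rnorm(50), 10, 5)
    vals[sample(50, 10)] <- NA
    m <- MeasureMatrix(vals, batch = rep(c("p", "q"), each = 5))
    z <- zscoreByBatch(m)
    expect_identical(unname(is.na(measureValues(z))), is.na(vals))
    # within one batch the transform is affine: correlation 1 per column
    for (j in 1:5) {
        rows <- batchLabels(m) == "p" & !is.na(vals[, j])
        if (sum(rows) > 2)
            expect_equal(abs(cor(vals[rows, j],
                                 measureValues(z)[rows, j])), 1)
    }
})
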