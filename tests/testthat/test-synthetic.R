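test_that("measure generator respects the spec and is deterministic", {
    spec <- measureTruthSpec(nIndividuals = 50,
        groups = data.frame(group = "g", nMeasures = 5, nFactors = 1,
                            loading = 0.8),
        missingRate = 0, seed = 7)
    m1 <- simulateMeasureMatrix(spec)
    m2 <- simulateMeasureMatrix(spec)
    expect_identical(measureValues(m1), measureValues(m2))
    expect_false(anyNA(measureValues(m1)))

    specMiss <- measureTruthSpec(nIndividuals = 400,
        groups = data.frame(group = "g", nMeasures = 8, nFactors = 1,
                            loading = 0.8),
        missingRate = 0.3, seed = 8)
    mm <- simulateMeasureMatrix(specMiss)
    frac <- mean(is.na(measureValues(mm)))
    # binomial CI on 3200 cells
    expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 3200))
})

test_that("generator rejects invalid specs", {
    g <- data.frame(group = "g", nMeasures = 5, nFactors = 1, loading = 0.8)
    expect_error(measureTruthSpec(10, g,
        batches = data.frame(batch = "b", size = 9, meanShift = 0,
                             varScale = 1)), "sum")
    expect_error(measureTruthSpec(10, g,
        batches = data.frame(batch = c("a", "b"), size = c(10, 0),
                             meanShift = 0, varScale = 1)), "sum|zero")
    expect_error(measureTruthSpec(10,
        data.frame(group = "g", nMeasures = 0, nFactors = 1,
                   loading = 0.8)), "zero")
    expect_error(measureTruthSpec(10, g, missingRate = 1.2), "missingRate")
})

test_that("generated correlations match the specified block structure", {
    spec <- measureTruthSpec(nIndividuals = 2000,
        groups = data.frame(group = c("g1", "g2"), nMeasures = c(5, 5),
                            nFactors = 1, loading = 0.9),
        missingRate = 0, noiseSd = 0.2, seed = 21)
    m <- simulateMeasureMatrix(spec)
    r <- cor(measureValues(m), method = "spearman")
    within <- c(r[1:5, 1:5][upper.tri(diag(5))],
                r[6:10, 6:10][upper.tri(diag(5))])
    cross <- as.vector(r[1:5, 6:10])
    expect_true(all(abs(within) > 0.5))
    expect_true(all(abs(cross) < 0.1))
})

test_that("empirical correlation converges to the ground truth", {
    spec <- measureTruthSpec(nIndividuals = 10000,
        groups = data.frame(group = c("a", "b"), nMeasures = c(5, 5),
                            nFactors = c(1, 2), loading = c(0.8, 0.6)),
        crossGroupEdges = data.frame(i = 1, j = 6, r = 0.4),
        missingRate = 0, seed = 31)
    m <- simulateMeasureMatrix(spec)
    truth <- S4Vectors::metadata(m)$truth$correlation
    emp <- cor(measureValues(m))
    expect_lt(norm(emp - truth, type = "F"), 0.25)
})

test_that("batch effects shift mean and scale variance as specified", {
    spec <- measureTruthSpec(nIndividuals = 2000,
        groups = data.frame(group = "g", nMeasures = 4, nFactors = 1,
                            loading = 0.5),
        batches = data.frame(batch = c("b1", "b2"), size = 1000,
                             meanShift = c(0, 10), varScale = c(1, 4)),
        missingRate = 0, seed = 41)
    m <- simulateMeasureMatrix(spec)
    v <- measureValues(m)
    b2 <- v[batchLabels(m) == "b2", 1]
    b1 <- v[batchLabels(m) == "b1", 1]
    expect_gt(mean(b2) - mean(b1), 9)
    expect_gt(var(b2) / var(b1), 2.5)
})

test_that("turn sequences follow the Markov flip model", {
    expect_error(simulateTurnSequences(1, 1), "at least 2")

    alt <- simulateTurnSequences(1, 100, switchProb = 1, seed = 1)[[1]]
    d <- turnDirections(alt)
    expect_true(all(d[-1] != d[-length(d)]))

    fair <- simulateTurnSequences(1, 20000, switchProb = 0.5, seed = 2)[[1]]
    d <- turnDirections(fair)
    fracSwitch <- mean(d[-1] != d[-length(d)])
    expect_lt(abs(fracSwitch - 0.5), 0.02)

    pois <- simulateTurnSequences(1, 50000, switchProb = 0.5,
                                  timing = "poisson", seed = 3)[[1]]
    iti <- diff(turnTimes(pois))
    expect_lt(abs(sd(iti) / mean(iti) - 1), 0.02)
})

test_that("expression generator plants recoverable couplings", {
    b <- makeBlockMatrix(n = 100, seed = 51)
    es0 <- expressionTruthSpec(nGenes = 50, fracCoupled = 0.1,
                               effectSize = 0, seed = 52)
    ed0 <- simulateExpression(es0, b)
    expect_equal(nrow(S4Vectors::metadata(ed0)$registry), 0L)

    es <- expressionTruthSpec(nGenes = 200, fracCoupled = 0.05,
                              effectSize = 1, seed = 53)
    ed <- simulateExpression(es, b)
    reg <- S4Vectors::metadata(ed)$registry
    expect_gt(nrow(reg), 0L)
    edn <- filterAndNormalize(ed)
    scr <- fitGeneBehaviorModels(edn, b)
    tab <- as.data.frame(screenTable(scr))
    planted <- merge(reg, tab, by = c("gene", "behavior"))
    expect_true(all(planted$p < 0.05))

    expect_warning(simulateExpression(
        expressionTruthSpec(nGenes = 5, fracCoupled = 0.01,
                            effectSize = 1, pathwaySizes = 2,
                            seed = 54), b),
        "no couplings")
})

test_that("RPM normalization removes library-size effects on recovery", {
    b <- makeBlockMatrix(n = 100, seed = 61)
    es <- expressionTruthSpec(nGenes = 150, fracCoupled = 0.05,
                              effectSize = 1, seed = 62)
    ed <- simulateExpression(es, b)
    lib <- S4Vectors::metadata(ed)$librarySizes
    expect_gt(max(lib) / min(lib), 1.5)
    reg <- S4Vectors::metadata(ed)$registry
    edn <- filterAndNormalize(ed, minReads = 0)
    scr <- fitGeneBehaviorModels(edn, b)
    tab <- as.data.frame(screenTable(scr))
    planted <- merge(reg, tab, by = c("gene", "behavior"))
    expect_gte(mean(planted$p < 0.05), 0.9)

    # raw counts carry the library-size signal the normalization removes
    cts <- SummarizedExperiment::assay(ed, "counts")
    rpm <- SummarizedExperiment::assay(edn, "rpm")[rownames(cts), ]
    depth <- colSums(cts)
    rRaw <- mean(abs(apply(cts, 1, cor, y = depth)))
    rRpm <- mean(abs(apply(rpm, 1, cor, y = depth)))
    expect_gt(rRaw, 0.6)
    expect_lt(rRpm, rRaw / 2)
})

test_that("pathway generator enriches the designated set", {
    es <- expressionTruthSpec(nGenes = 100, fracCoupled = 0.2,
                              effectSize = 1,
                              pathwaySizes = c(20, 20, 20), seed = 71)
    coupled <- sprintf("gene_%05d", 1:20)
    sets <- simulatePathways(es, coupled, enrichedFraction = 1)
    expect_length(intersect(sets[[1]], coupled), 20)
    er <- enrich(coupled, sprintf("gene_%05d", 1:100), sets)
    expect_lt(er$p[er$set == "pathway_01"], 0.05)

    setsNull <- simulatePathways(es, coupled, enrichedFraction = 0)
    ovNull <- length(intersect(setsNull[[1]], coupled))
    expect_lt(ovNull, 15)   # no deliberate loading
})
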