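test_that("read-count filtering applies the documented cutoffs", {
    set.seed(61)
    counts <- matrix(rpois(5 * 4, 100), 5, 4,
                     dimnames = list(paste0("g", 1:5), paste0("i", 1:4)))
    # individual 4 one read short of the cutoff
    tot <- colSums(counts)
    counts <- sweep(counts, 2, floor(1.1e6 / tot), "*")
    counts[, 4] <- round(counts[, 4] * (999999 / sum(counts[, 4])))
    stopifnot(sum(counts[, 4]) <= 999999)
    ed <- filterAndNormalize(counts, minReads = 1e6, minMeanRpm = 0)
    expect_false("i4" %in% colnames(SummarizedExperiment::assay(ed)))
    expect_true("i4" %in% S4Vectors::metadata(ed)$droppedIndividuals)

    # low-RPM gene dropped: mean RPM over retained individuals below 10
    counts2 <- matrix(1e5, 3, 3,
                      dimnames = list(paste0("g", 1:3), paste0("i", 1:3)))
    counts2[3, ] <- 1   # ~3 RPM
    counts2 <- rbind(counts2, filler = 2e6 - colSums(counts2))
    ed2 <- filterAndNormalize(counts2, minReads = 1e6, minMeanRpm = 10)
    expect_false("g3" %in% rownames(SummarizedExperiment::assay(ed2)))
})

test_that("RPM is scale invariant per individual", {
    counts <- matrix(c(10, 30, 20, 40), 2, 2,
                     dimnames = list(c("g1", "g2"), c("i1", "i2")))
    ed <- filterAndNormalize(counts, minReads = 0, minMeanRpm = 0)
    rpm <- SummarizedExperiment::assay(ed, "rpm")
    ed2 <- filterAndNormalize(cbind(i1 = counts[, 1] * 2,
                                    i2 = counts[, 2]),
                              minReads = 0, minMeanRpm = 0)
    expect_equal(SummarizedExperiment::assay(ed2, "rpm")[, "i1"],
                 rpm[, "i1"])
})

test_that("quantile normalization matches mean order statistics and is idempotent", {
    counts <- matrix(c(1, 2, 3, 4), 2, 2,
                     dimnames = list(c("g1", "g2"), c("i1", "i2")))
    ed <- filterAndNormalize(counts, minReads = 0, minMeanRpm = 0)
    norm <- SummarizedExperiment::assay(ed, "normalized")
    # per-column RPM distributions are (.33M, .67M) and (.43M, .57M);
    # rank-aligned means give both individuals the same sorted vector
    expect_equal(sort(norm[, 1]), sort(norm[, 2]), ignore_attr = TRUE)
    expect_equal(norm[, 1],
                 c(g1 = mean(c(1/3, 3/7)), g2 = mean(c(2/3, 4/7))) * 1e6)

    again <- limma::normalizeQuantiles(norm, ties = TRUE)
    expect_equal(unname(again), unname(norm), tolerance = 1e-12)
})

test_that("screen recovers exact affine relationships and calibrates at null", {
    set.seed(62)
    n <- 50
    norm <- matrix(rexp(20 * n, 1 / 100), 20, n,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("ind_%03d", 1:n)))
    ed <- ExpressionDataset(round(norm), normalized = norm)
    b <- matrix(c(3 * norm[1, ] - 5, rnorm(n)), n, 2,
                dimnames = list(colnames(norm), NULL))
    bm <- MeasureMatrix(b, assay = "ymaze", measure = c("aff", "noise"))
    scr <- fitGeneBehaviorModels(ed, bm)
    tab <- as.data.frame(screenTable(scr))
    affRow <- tab[tab$gene == "g01" & grepl("aff", tab$behavior), ]
    expect_equal(affRow$r2, 1, tolerance = 1e-10)
    expect_equal(affRow$slope, 3, tolerance = 1e-8)
    expect_equal(affRow$p, 0)

    # zero-variance behavior flagged, not fit
    bconst <- MeasureMatrix(matrix(1, n, 1,
                                   dimnames = list(colnames(norm), NULL)),
                            assay = "ymaze", measure = "const")
    scrC <- fitGeneBehaviorModels(ed, bconst)
    expect_true(all(screenTable(scrC)$flagged))
})

test_that("significant gene lists respect the p threshold", {
    b <- makeBlockMatrix(n = 80, seed = 191)
    es <- expressionTruthSpec(nGenes = 100, fracCoupled = 0.05,
                              effectSize = 1, seed = 63)
    ed <- filterAndNormalize(simulateExpression(es, b))
    scr <- fitGeneBehaviorModels(ed, b)
    tab <- as.data.frame(screenTable(scr))
    for (bh in unique(tab$behavior)[1:2]) {
        lst <- significantGenes(scr, bh)
        sub <- tab[tab$behavior == bh & !tab$flagged, ]
        expect_setequal(lst, sub$gene[sub$p < 0.05])
    }
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
    # printed example: background 10, set 4, list 5, overlap 4
    bg <- sprintf("g%02d", 1:10)
    er <- enrich(bg[1:5], bg, list(s = bg[1:4]))
    expect_equal(er$p, 6 / 252)
    expect_equal(er$p, hypergeomEnumeration(10, 4, 5, 4))

    set.seed(64)
    for (k in 1:10) {
        N <- sample(5:12, 1)
        K <- sample(2:(N - 1), 1)
        nL <- sample(1:(N - 1), 1)
        bgk <- sprintf("x%02d", 1:N)
        lst <- sample(bgk, nL)
        ov <- length(intersect(lst, bgk[1:K]))
        p <- enrich(lst, bgk, list(s = bgk[1:K]))$p
        expect_equal(p, hypergeomEnumeration(N, K, nL, ov),
                     tolerance = 1e-12)
    }
})

test_that("enrichment edge cases and BH adjustment", {
    bg <- sprintf("g%02d", 1:10)
    # list = background: every p = 1
    erFull <- enrich(bg, bg, list(a = bg[1:3], b = bg[4:9]))
    expect_equal(erFull$p, c(1, 1))
    # empty list: all p = 1
    erEmpty <- enrich(character(), bg, list(a = bg[1:3]))
    expect_equal(erEmpty$p, 1)
    # BH step-up on (0.01, 0.02, 0.03, 0.04) over 4 sets -> all 0.04
    expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
                 rep(0.04, 4))
    expect_true(all(enrich(bg[1:5], bg,
        list(a = bg[1:4], b = bg[2:5], c = bg[5:9],
             d = bg[6:9]))$padj >=
        enrich(bg[1:5], bg,
        list(a = bg[1:4], b = bg[2:5], c = bg[5:9],
             d = bg[6:9]))$p))
})

test_that("bootstrap enrichment separates planted pathways from shuffled controls", {
    b <- makeBlockMatrix(n = 100, seed = 201)
    es <- expressionTruthSpec(nGenes = 120, fracCoupled = 0.15,
                              effectSize = 1.2,
                              pathwaySizes = c(15, 15, 15), seed = 65)
    ed0 <- simulateExpression(es, b)
    reg <- S4Vectors::metadata(ed0)$registry
    ed <- filterAndNormalize(ed0)
    sets <- simulatePathways(es, reg$gene, enrichedFraction = 1,
                             geneUniverse = rownames(ed))
    boot <- bootstrapEnrichment(ed, b, sets, nBoot = 20, seed = 66)
    shuf <- bootstrapEnrichment(ed, b, sets, nBoot = 20, seed = 66,
                                shuffle = TRUE)
    pPlanted <- max(boot$bootProb$prob[boot$bootProb$set == "pathway_01"])
    pShuf <- max(shuf$bootProb$prob[shuf$bootProb$set == "pathway_01"])
    expect_gt(pPlanted, 0.8)
    expect_lt(pShuf, 0.3)
    expect_gt(boot$setSummary$avgMaxNegLogP[1],
              shuf$setSummary$avgMaxNegLogP[1])

    expect_error(bootstrapEnrichment(ed, b, sets, nBoot = 1), "at least 2")
    # pipeline default follows the 500-replicate bootstrap protocol
    expect_equal(eval(formals(bootstrapEnrichment)$nBoot), 500L)
})
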