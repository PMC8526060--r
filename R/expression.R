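## Transcriptome arm: normalization and filtering, the single-gene linear
## model screen against behaviors, hypergeometric gene-set enrichment with
## Benjamini-Hochberg adjustment, and bootstrap enrichment summaries.

#' Filter and normalize a read-count matrix
#'
#' Individuals with fewer than `minReads` total reads are dropped; counts
#' are converted to reads per million (RPM, per-individual library-size
#' normalization); genes with mean RPM below `minMeanRpm` over the
#' retained individuals are dropped; and the remaining RPM matrix is
#' quantile normalized (average-rank ties) so all individuals share an
#' identical expression distribution.
#'
#' @param counts gene x individual non-negative count matrix, or an
#'   \linkS4class{ExpressionDataset}.
#' @param minReads per-individual total-read cutoff (default 1e6).
#' @param minMeanRpm mean-RPM gene cutoff (default 10).
#' @return An \linkS4class{ExpressionDataset} with `counts`, `rpm` and
#'   `normalized` assays; dropped ids are recorded in `metadata()`.
#' @export
filterAndNormalize <- function(counts, minReads = 1e6, minMeanRpm = 10) {
    meta <- list()
    if (is(counts, "ExpressionDataset")) {
        meta <- metadata(counts)
        counts <- SummarizedExperiment::assay(counts, "counts")
    }
    counts <- as.matrix(counts)
    if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")

    libSize <- colSums(counts)
    keepInd <- libSize >= minReads
    if (!any(keepInd)) stop("all individuals fall below the read cutoff")
    cts <- counts[, keepInd, drop = FALSE]

    rpm <- sweep(cts, 2L, colSums(cts), "/") * 1e6
    keepGene <- rowMeans(rpm) >= minMeanRpm
    if (!any(keepGene)) stop("all genes fall below the mean-RPM cutoff")
    cts <- cts[keepGene, , drop = FALSE]
    rpm <- rpm[keepGene, , drop = FALSE]

    norm <- limma::normalizeQuantiles(rpm, ties = TRUE)
    dimnames(norm) <- dimnames(rpm)

    ed <- ExpressionDataset(cts, rpm = rpm, normalized = norm)
    metadata(ed) <- c(meta, list(
        droppedIndividuals = colnames(counts)[!keepInd],
        droppedGenes = rownames(counts)[!keepGene],
        minReads = minReads, minMeanRpm = minMeanRpm))
    ed
}

## Vectorized per-gene OLS of y on each row of X (genes x n).
## Returns slope, r2 and two-tailed slope p per gene.
geneWiseOls <- function(X, y) {
    ok <- !is.na(y)
    y <- y[ok]; X <- X[, ok, drop = FALSE]
    n <- length(y)
    sy <- sd(y)
    cx <- X - rowMeans(X)
    sx <- sqrt(rowSums(cx^2) / (n - 1))
    r <- as.vector(cx %*% (y - mean(y))) / ((n - 1) * sx * sy)
    flagged <- !is.finite(r) | sx == 0
    if (sy == 0 || n < 4L) flagged <- rep(TRUE, nrow(X))
    r[flagged] <- NA_real_
    r <- pmin(pmax(r, -1), 1)
    slope <- r * sy / sx
    tval <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * pt(-abs(tval), df = n - 2)
    p[!is.na(r) & abs(r) >= 1 - 1e-12] <- 0
    data.frame(slope = slope, r2 = r^2, p = p, flagged = flagged, n = n)
}

#' Single-gene linear-model screen of behaviors on expression
#'
#' Fits one ordinary-least-squares model per (gene, behavior) pair,
#' predicting the behavioral score from the gene's normalized expression
#' across the individuals shared by both datasets. Individuals missing a
#' behavior are dropped for that behavior's models. No multiple-testing
#' correction is applied at this stage; per-behavior significant gene
#' lists are thresholded at raw model p < `alpha`.
#'
#' @param expr an \linkS4class{ExpressionDataset} with a `normalized`
#'   assay (see [filterAndNormalize()]).
#' @param behaviors a \linkS4class{MeasureMatrix} (individual ids must
#'   overlap the expression columns in >= 4 individuals).
#' @param alpha per-model significance threshold (default 0.05).
#' @return A \linkS4class{ModelScreenResult}.
#' @export
fitGeneBehaviorModels <- function(expr, behaviors, alpha = 0.05) {
    stopifnot(is(expr, "ExpressionDataset"))
    if (!"normalized" %in% SummarizedExperiment::assayNames(expr))
        stop("expression must be normalized first (filterAndNormalize)")
    X <- SummarizedExperiment::assay(expr, "normalized")
    B <- asValuesMatrix(behaviors)
    shared <- intersect(colnames(X), rownames(B))
    if (length(shared) < 4L)
        stop("at least 4 shared individuals are required")
    X <- X[, shared, drop = FALSE]
    B <- B[shared, , drop = FALSE]

    tabs <- lapply(seq_len(ncol(B)), function(j) {
        fit <- geneWiseOls(X, B[, j])
        cbind(data.frame(gene = rownames(X),
                         behavior = colnames(B)[j]), fit)
    })
    tab <- do.call(rbind, tabs)
    rownames(tab) <- NULL
    new("ModelScreenResult", table = DataFrame(tab), alpha = alpha)
}

#' Hypergeometric gene-set enrichment of one gene list
#'
#' For each gene set, computes the upper-tail hypergeometric probability
#' of observing at least the actual overlap between the gene list and the
#' set, given the background universe, then adjusts across sets by
#' Benjamini-Hochberg.
#'
#' @param geneList character vector of hit genes (a subset of
#'   `background`).
#' @param background character vector: the gene universe (typically the
#'   post-filter genes).
#' @param geneSets named list of character vectors (see [readGmt()]);
#'   sets are intersected with the background.
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return data.frame with one row per set: `set`, `overlap`, `setSize`,
#'   `listSize`, `p`, `padj`, `significant`. An empty gene list gives all
#'   p = 1.
#' @examples
#' bg <- sprintf("g%02d", 1:10)
#' enrich(bg[1:5], bg, list(s1 = bg[1:4]))
#' @export
enrich <- function(geneList, background, geneSets, alpha = 0.05) {
    geneList <- intersect(geneList, background)
    N <- length(background)
    nL <- length(geneList)
    res <- lapply(names(geneSets), function(s) {
        set <- intersect(geneSets[[s]], background)
        K <- length(set)
        ov <- length(intersect(geneList, set))
        p <- if (nL == 0L || K == 0L) 1
             else phyper(ov - 1L, K, N - K, nL, lower.tail = FALSE)
        data.frame(set = s, overlap = ov, setSize = K, listSize = nL,
                   p = p)
    })
    out <- do.call(rbind, res)
    out$padj <- p.adjust(out$p, method = "BH")
    out$significant <- out$padj < alpha
    rownames(out) <- NULL
    out
}

#' Bootstrap reproducibility of gene-set enrichment
#'
#' Re-runs the screen and the per-behavior enrichment on `nBoot` bootstrap
#' resamples of individuals (drawn downstream of quantile normalization),
#' recording per (set, behavior) the fraction of replicates in which the
#' set is significantly enriched, and per set the mean over replicates of
#' the maximum `-log10` adjusted p over behaviors. With
#' `shuffle = TRUE`, behavior rows are permuted before each screen,
#' giving a null control.
#'
#' @param expr \linkS4class{ExpressionDataset} with a `normalized` assay.
#' @param behaviors \linkS4class{MeasureMatrix}.
#' @param geneSets named list of gene sets.
#' @param nBoot bootstrap replicates (default 500; >= 2 required).
#' @param seed integer seed.
#' @param alpha screen and enrichment threshold.
#' @param shuffle permute individuals' behavior rows before each screen.
#' @return List with `bootProb` (data.frame set x behavior significance
#'   probabilities) and `setSummary` (data.frame per set with
#'   `avgMaxNegLogP`).
#' @export
bootstrapEnrichment <- function(expr, behaviors, geneSets, nBoot = 500L,
                                seed = 1L, alpha = 0.05, shuffle = FALSE) {
    if (nBoot < 2L) stop("nBoot must be at least 2")
    X <- SummarizedExperiment::assay(expr, "normalized")
    B <- asValuesMatrix(behaviors)
    shared <- intersect(colnames(X), rownames(B))
    if (length(shared) < 4L)
        stop("at least 4 shared individuals are required")
    X <- X[, shared, drop = FALSE]
    B <- B[shared, , drop = FALSE]
    background <- rownames(X)
    behaviorsNames <- colnames(B)
    setNamesV <- names(geneSets)

    set.seed(as.integer(seed))
    sigArr <- array(0, dim = c(length(setNamesV), length(behaviorsNames)),
                    dimnames = list(setNamesV, behaviorsNames))
    maxNegLog <- matrix(NA_real_, nBoot, length(setNamesV),
                        dimnames = list(NULL, setNamesV))
    n <- length(shared)
    for (bb in seq_len(nBoot)) {
        idx <- sample.int(n, n, replace = TRUE)
        Bb <- B[idx, , drop = FALSE]
        if (shuffle) Bb <- Bb[sample.int(n), , drop = FALSE]
        Xb <- X[, idx, drop = FALSE]
        negLog <- matrix(0, length(setNamesV), length(behaviorsNames))
        for (j in seq_along(behaviorsNames)) {
            fit <- geneWiseOls(Xb, Bb[, j])
            hits <- background[!fit$flagged & !is.na(fit$p) &
                               fit$p < alpha]
            er <- enrich(hits, background, geneSets, alpha = alpha)
            er <- er[match(setNamesV, er$set), ]
            sigArr[, j] <- sigArr[, j] + as.numeric(er$significant)
            negLog[, j] <- -log10(pmax(er$padj, 1e-300))
        }
        maxNegLog[bb, ] <- apply(negLog, 1L, max)
    }
    bootProb <- data.frame(
        set = rep(setNamesV, times = length(behaviorsNames)),
        behavior = rep(behaviorsNames, each = length(setNamesV)),
        prob = as.vector(sigArr / nBoot))
    setSummary <- data.frame(set = setNamesV,
                             avgMaxNegLogP = colMeans(maxNegLog))
    list(bootProb = bootProb, setSummary = setSummary, nBoot = nBoot,
         shuffle = shuffle)
}
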