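## Correlation statistics: Spearman matrices with t-transform p-values,
## bootstrap kernel-density FDR curves, and cross-dataset
## correlation-of-correlations.

## Two-tailed p-value for a correlation via the t-transform
## t = r * sqrt((n - 2) / (1 - r^2)).
corPValue <- function(r, n) {
    p <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
    ok <- !is.na(r) & n >= 3
    unit <- ok & abs(r) >= 1 - 1e-12
    p[unit] <- 0              # |r| = 1: t undefined, flagged p = 0
    mid <- ok & !unit
    tval <- r[mid] * sqrt((n[mid] - 2) / (1 - r[mid]^2))
    p[mid] <- 2 * pt(-abs(tval), df = n[mid] - 2)
    attr(p, "unitR") <- which(unit & upper.tri(r), arr.ind = TRUE)
    p
}

#' Spearman rank correlation matrix with p-values
#'
#' Computes all pairwise Spearman correlations (average ranks on ties) and
#' two-tailed p-values from the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`. With missing entries, pairwise
#' complete observations are used. Pairs with `|r| = 1` are reported with
#' p = 0 (flagged in `attr(pMatrix(res), "unitR")`); constant columns give
#' undefined correlations, reported missing.
#'
#' @param m numeric matrix (individuals x measures),
#'   \linkS4class{MeasureMatrix} or \linkS4class{DistilledMatrix}.
#' @return A \linkS4class{CorrelationResult}.
#' @examples
#' r <- spearmanMatrix(matrix(rnorm(100), 20, 5))
#' diag(corMatrix(r))
#' @export
spearmanMatrix <- function(m) {
    v <- asValuesMatrix(m)
    if (ncol(v) < 2L) stop("at least two measures are required")
    n <- crossprod(!is.na(v))
    if (any(n[upper.tri(n)] < 3L))
        warning("pair(s) with fewer than 3 complete observations")
    r <- suppressWarnings(
        cor(v, method = "spearman", use = "pairwise.complete.obs"))
    diag(r) <- 1
    p <- corPValue(r, n)
    diag(p) <- NA_real_
    new("CorrelationResult", r = r, p = p,
        n = matrix(as.numeric(n), nrow(n), dimnames = dimnames(n)))
}

## Boundary-reflected Gaussian KDE on [0, 1], Silverman bandwidth.
kdeUnitInterval <- function(p, grid) {
    p <- p[!is.na(p)]
    bw <- tryCatch(bw.nrd0(p), error = function(e) NA_real_)
    if (!is.finite(bw) || bw <= 0) bw <- 0.01
    dens <- density(c(p, -p, 2 - p), bw = bw, from = min(grid),
                    to = max(grid), n = length(grid))
    3 * dens$y
}

#' Bootstrap kernel-density false discovery rate for correlation matrices
#'
#' Estimates the FDR of calling a measure pair significantly correlated at
#' threshold `alpha`. The matrix is bootstrap resampled over individuals
#' (`nBoot` repetitions); the p-values of all unique measure pairs are
#' pooled into a mean boundary-reflected kernel density estimate. The same
#' procedure on column-shuffled (independence-null) matrices gives a null
#' density, and FDR(a) is the null density divided by the observed density
#' at a.
#'
#' @param m complete numeric matrix, \linkS4class{MeasureMatrix} or
#'   \linkS4class{DistilledMatrix}.
#' @param alpha working significance threshold (default 0.05).
#' @param nBoot bootstrap repetitions (default 100).
#' @param seed integer seed.
#' @param gridSize p-value grid resolution.
#' @param fdrMax cap applied where the observed density is near zero.
#' @param tailRatio if TRUE, estimate FDR from densities integrated over
#'   \[0, a\] (a tail-mass ratio) instead of the pointwise density ratio.
#' @return An \linkS4class{FDRCurve}; `nSignificant` counts unique pairs
#'   with p < alpha on the unresampled matrix.
#' @export
bootstrapFdr <- function(m, alpha = 0.05, nBoot = 100L, seed = 1L,
                         gridSize = 512L, fdrMax = 10, tailRatio = FALSE) {
    v <- asValuesMatrix(m)
    if (anyNA(v)) stop("matrix must be complete")
    n <- nrow(v); d <- ncol(v)
    grid <- seq(0, 1, length.out = gridSize)
    ut <- upper.tri(matrix(0, d, d))

    pairP <- function(x) {
        res <- spearmanMatrix(x)
        res@p[ut]
    }
    set.seed(as.integer(seed))
    obsDens <- matrix(0, nBoot, gridSize)
    nullDens <- matrix(0, nBoot, gridSize)
    for (b in seq_len(nBoot)) {
        idx <- sample.int(n, n, replace = TRUE)
        obsDens[b, ] <- kdeUnitInterval(pairP(v[idx, , drop = FALSE]), grid)
        shuf <- apply(v, 2L, function(col) col[sample.int(n)])
        idx2 <- sample.int(n, n, replace = TRUE)
        nullDens[b, ] <- kdeUnitInterval(pairP(shuf[idx2, , drop = FALSE]),
                                         grid)
    }
    obsBar <- colMeans(obsDens)
    nullBar <- colMeans(nullDens)

    if (tailRatio) {
        cum <- function(y) cumsum(y) / seq_along(y)
        fdr <- cum(nullBar) / pmax(cum(obsBar), 1e-12)
    } else {
        fdr <- nullBar / pmax(obsBar, 1e-12)
    }
    lowDens <- obsBar < 1e-6
    if (any(lowDens & fdr > fdrMax))
        warning("observed p-value density near zero; FDR capped at ",
                fdrMax)
    fdr <- pmin(fdr, fdrMax)

    fdrAt <- stats::approx(grid, fdr, xout = alpha, rule = 2)$y
    pObs <- pairP(v)
    new("FDRCurve", alphaGrid = grid, fdr = fdr,
        observedDensity = obsBar, nullDensity = nullBar,
        alpha = alpha, fdrAtAlpha = fdrAt,
        nSignificant = sum(pObs < alpha, na.rm = TRUE))
}

#' Bootstrap distribution of the correlation of correlations
#'
#' Measures how similar the correlation structures of two datasets sharing
#' the same measures are. Per repetition, individuals are resampled with
#' replacement independently within each matrix, each Spearman correlation
#' matrix is computed, the unique off-diagonal r-values are vectorized,
#' and the Spearman correlation between the two vectors is recorded.
#'
#' @param a,b \linkS4class{MeasureMatrix} objects (or matrices) with
#'   aligned measure columns; `a` and `b` may be the same object.
#' @param nReps bootstrap repetitions (default 100).
#' @param seed integer seed.
#' @param resample if FALSE, a single correlation of correlations on the
#'   unresampled matrices is returned.
#' @return Numeric vector of correlation-of-correlations values.
#' @export
corrOfCorrsBootstrap <- function(a, b, nReps = 100L, seed = 1L,
                                 resample = TRUE) {
    va <- asValuesMatrix(a); vb <- asValuesMatrix(b)
    if (is(a, "MeasureMatrix") && is(b, "MeasureMatrix")) {
        shared <- intersect(colnames(va), colnames(vb))
        if (length(shared) < 2L) stop("fewer than 2 shared measures")
        va <- va[, shared, drop = FALSE]
        vb <- vb[, shared, drop = FALSE]
    } else if (ncol(va) != ncol(vb)) {
        stop("matrices must have aligned measure columns")
    }
    if (ncol(va) < 2L) stop("fewer than 2 shared measures")
    ut <- upper.tri(matrix(0, ncol(va), ncol(va)))
    rVec <- function(x) {
        r <- suppressWarnings(
            cor(x, method = "spearman", use = "pairwise.complete.obs"))
        r[ut]
    }
    if (!resample) {
        return(suppressWarnings(
            cor(rVec(va), rVec(vb), method = "spearman",
                use = "complete.obs")))
    }
    set.seed(as.integer(seed))
    vapply(seq_len(nReps), function(k) {
        ia <- sample.int(nrow(va), nrow(va), replace = TRUE)
        ib <- sample.int(nrow(vb), nrow(vb), replace = TRUE)
        suppressWarnings(
            cor(rVec(va[ia, , drop = FALSE]), rVec(vb[ib, , drop = FALSE]),
                method = "spearman", use = "complete.obs"))
    }, numeric(1))
}
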