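## Distillation: collapse each a-priori measure group onto its
## shuffle-significant principal components.
##
## PC retention uses a parallel-analysis-style criterion: the observed
## per-rank variance-explained profile is compared with the profile of the
## same matrix after independently permuting every column across
## individuals (destroying inter-measure correlation while preserving
## marginals). The retained count is the longest prefix of ranks whose
## observed variance explained sits above or within the null confidence
## interval -- operationalized as at or above the null CI's lower bound.

zscoreColumns <- function(x) {
    mu <- colMeans(x)
    s <- apply(x, 2L, sd)
    s[s == 0 | !is.finite(s)] <- 1
    sweep(sweep(x, 2L, mu, "-"), 2L, s, "/")
}

## Variance-explained profile of the correlation-scale PCA of x.
veProfile <- function(xz) {
    ev <- eigen(stats::cov(xz), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    ev / sum(ev)
}

#' Count shuffle-significant principal components of a measure group
#'
#' Runs PCA on the correlation scale (columns z-scored) and compares each
#' rank's variance explained with a null ensemble built by independently
#' permuting every column across individuals `nShuffles` times. The
#' retained count is the highest rank `k` such that every rank up to `k`
#' has variance explained at or above the lower bound of the null
#' confidence interval at its rank; at least one PC is always retained.
#' PC signs are fixed by making each retained PC's largest-magnitude
#' loading positive.
#'
#' @param x numeric matrix (individuals x group measures) with no missing
#'   entries, or a \linkS4class{MeasureMatrix} (all its measures are used).
#' @param nShuffles number of column-shuffle null replicates.
#' @param ciLevel confidence level of the null interval.
#' @param seed integer seed for the shuffles.
#' @param group group name recorded in the result.
#' @return A \linkS4class{PCSelection}.
#' @examples
#' f <- rnorm(300)
#' x <- cbind(f + rnorm(300, sd = 0.3), f + rnorm(300, sd = 0.3),
#'            rnorm(300))
#' nSignificant(significantPCCount(x, nShuffles = 100, seed = 1))
#' @export
significantPCCount <- function(x, nShuffles = 250L, ciLevel = 0.95,
                               seed = 1L, group = "group") {
    if (is(x, "MeasureMatrix")) x <- x@values
    x <- as.matrix(x)
    if (anyNA(x)) stop("group submatrix must be complete (impute first)")
    if (nrow(x) < 2L) stop("at least 2 individuals are required")
    d <- ncol(x)
    if (d == 1L) {
        return(new("PCSelection", group = group, nMeasures = 1L,
                   nSignificant = 1L,
                   loadings = matrix(1, 1, 1,
                                     dimnames = list(colnames(x), "PC1")),
                   varianceExplained = 1,
                   nullLower = NA_real_, nullUpper = NA_real_))
    }
    xz <- zscoreColumns(x)
    eg <- eigen(stats::cov(xz), symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    ve <- ev / sum(ev)

    set.seed(as.integer(seed))
    nullVe <- matrix(NA_real_, nShuffles, d)
    n <- nrow(xz)
    for (s in seq_len(nShuffles)) {
        shuf <- apply(xz, 2L, function(col) col[sample.int(n)])
        nullVe[s, ] <- veProfile(shuf)
    }
    alpha <- (1 - ciLevel) / 2
    lower <- apply(nullVe, 2L, quantile, probs = alpha)
    upper <- apply(nullVe, 2L, quantile, probs = 1 - alpha)

    aboveOrWithin <- ve >= lower
    k <- if (aboveOrWithin[1L]) {
        runs <- rle(aboveOrWithin)
        if (runs$values[1L]) runs$lengths[1L] else 1L
    } else 1L
    k <- max(1L, as.integer(k))

    load <- eg$vectors[, seq_len(k), drop = FALSE]
    # Deterministic sign: largest-magnitude loading positive.
    for (j in seq_len(k)) {
        imax <- which.max(abs(load[, j]))
        if (load[imax, j] < 0) load[, j] <- -load[, j]
    }
    dimnames(load) <- list(colnames(x), paste0("PC", seq_len(k)))
    new("PCSelection", group = group, nMeasures = d, nSignificant = k,
        loadings = load, varianceExplained = ve,
        nullLower = lower, nullUpper = upper)
}

#' Distill a complete MeasureMatrix onto significant group PCs
#'
#' Replaces each a-priori group's submatrix (group labels from
#' `groupLabels(m)` unless `groups` is supplied) with its projection onto
#' the group's shuffle-significant principal components; ungrouped
#' measures pass through unchanged. Output columns are re-z-scored.
#'
#' @param m a complete (no missing entries) \linkS4class{MeasureMatrix}.
#' @param groups optional named list mapping group name to measure keys;
#'   defaults to the `group` column of `measureInfo(m)`.
#' @param nShuffles,ciLevel,seed passed to [significantPCCount()].
#' @return A \linkS4class{DistilledMatrix}.
#' @export
distill <- function(m, groups = NULL, nShuffles = 250L, ciLevel = 0.95,
                    seed = 1L) {
    stopifnot(is(m, "MeasureMatrix"))
    v <- m@values
    if (anyNA(v)) stop("matrix must be complete before distillation")
    keys <- colnames(v)
    if (is.null(groups)) {
        gl <- groupLabels(m)
        groups <- split(keys[!is.na(gl)], gl[!is.na(gl)])
    }
    bad <- setdiff(unlist(groups), keys)
    if (length(bad))
        stop("group(s) reference unknown measure key(s): ",
             paste(head(bad, 5), collapse = ", "))
    if (any(lengths(groups) == 0L)) stop("empty a-priori group")

    grouped <- unlist(groups, use.names = FALSE)
    ungrouped <- setdiff(keys, grouped)

    cols <- list(); prov <- list(); selections <- list()
    set.seed(as.integer(seed))
    groupSeeds <- sample.int(.Machine$integer.max - 1L,
                             length(groups))
    for (gi in seq_along(groups)) {
        g <- names(groups)[gi]
        sub <- v[, groups[[g]], drop = FALSE]
        sel <- significantPCCount(sub, nShuffles = nShuffles,
                                  ciLevel = ciLevel,
                                  seed = groupSeeds[gi], group = g)
        scores <- zscoreColumns(sub) %*% sel@loadings
        colnames(scores) <- paste(g, colnames(sel@loadings), sep = ".")
        cols[[g]] <- scores
        prov[[g]] <- DataFrame(group = g,
                               pc = seq_len(sel@nSignificant),
                               source = "pc")
        selections[[g]] <- sel
    }
    if (length(ungrouped)) {
        cols[["__ungrouped__"]] <- v[, ungrouped, drop = FALSE]
        prov[["__ungrouped__"]] <- DataFrame(
            group = rep(NA_character_, length(ungrouped)),
            pc = rep(NA_integer_, length(ungrouped)),
            source = rep("measure", length(ungrouped)))
    }
    out <- do.call(cbind, unname(cols))
    out <- zscoreColumns(out)
    rownames(out) <- rownames(v)
    provenance <- do.call(rbind, unname(prov))
    rownames(provenance) <- colnames(out)
    new("DistilledMatrix", values = out, provenance = provenance,
        selections = selections)
}
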