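# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: component counts come from transitive closure,
# correlation p-values from exhaustive permutation, hypergeometric tails
# from subset enumeration.

# Connected-component count of a symmetric adjacency matrix via boolean
# transitive closure (reachability), independent of the union-find sweep.
componentCountClosure <- function(adj) {
    d <- nrow(adj)
    reach <- (adj | diag(d)) * 1
    for (k in seq_len(ceiling(log2(max(d, 2))))) {
        reach <- (reach %*% reach > 0) * 1
    }
    nrow(unique(reach))
}

# Full spectrum oracle: thresholds as the implementation defines them,
# components by closure at each threshold.
spectrumOracle <- function(r, thresholds) {
    a <- abs(r)
    vapply(thresholds, function(t) {
        adj <- a > t
        diag(adj) <- FALSE
        componentCountClosure(adj)
    }, numeric(1))
}

# Exact permutation p-value for the Spearman correlation of small samples:
# the proportion of all orderings of y whose |r| is at least the observed.
spearmanPermutationP <- function(x, y) {
    rObs <- cor(x, y, method = "spearman")
    perms <- permutationsOf(length(y))
    rAll <- apply(perms, 1L, function(idx)
        cor(x, y[idx], method = "spearman"))
    mean(abs(rAll) >= abs(rObs) - 1e-12)
}

permutationsOf <- function(n) {
    if (n == 1L) return(matrix(1L, 1, 1))
    sub <- permutationsOf(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
        cbind(k, sub + (sub >= k))
    }))
}

# Hypergeometric upper-tail probability by exhaustive enumeration of all
# possible gene lists of the drawn size (backgrounds <= 12 genes).
hypergeomEnumeration <- function(N, K, nDraw, minOverlap) {
    draws <- combn(N, nDraw)
    inSet <- seq_len(K)                     # WLOG the set is genes 1..K
    overlaps <- apply(draws, 2L, function(g) sum(g %in% inSet))
    mean(overlaps >= minOverlap)
}

# Shared fixture: small complete behavioral matrix with two correlated
# blocks, built from the generator with a fixed seed.
makeBlockMatrix <- function(n = 120, loading = 0.85, seed = 402) {
    spec <- measureTruthSpec(nIndividuals = n,
        groups = data.frame(group = c("blockA", "blockB"),
                            nMeasures = c(4, 4), nFactors = 1,
                            loading = loading),
        missingRate = 0, seed = seed)
    simulateMeasureMatrix(spec)
}
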