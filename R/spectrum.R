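## Connected-components spectrum: the dimensionality profile of a
## correlation matrix.
##
## At a threshold t, measures i and j are joined by an edge when
## |r_ij| > t; the number of connected components of that graph is the
## effective dimensionality at t. Sweeping thresholds from the minimum to
## the maximum off-diagonal |r| yields a step function of counts, and the
## histogram of counts over the sweep profiles organization across all
## dimensionalities 1..d.
##
## The sweep is computed incrementally: thresholds are visited in
## decreasing order while edges are added (union-find) as they exceed the
## current threshold, so the whole spectrum costs one sort plus one pass
## over the edges.

unionFindCounts <- function(d, edgeI, edgeJ, edgeW, thresholds) {
    parent <- seq_len(d)
    find <- function(a) {
        while (parent[a] != a) {
            parent[a] <<- parent[parent[a]]
            a <- parent[a]
        }
        a
    }
    ord <- order(edgeW, decreasing = TRUE)
    edgeI <- edgeI[ord]; edgeJ <- edgeJ[ord]; edgeW <- edgeW[ord]
    tOrd <- order(thresholds, decreasing = TRUE)
    counts <- integer(length(thresholds))
    comp <- d
    e <- 1L
    for (k in tOrd) {
        t <- thresholds[k]
        while (e <= length(edgeW) && edgeW[e] > t) {
            ra <- find(edgeI[e]); rb <- find(edgeJ[e])
            if (ra != rb) {
                parent[ra] <- rb
                comp <- comp - 1L
            }
            e <- e + 1L
        }
        counts[k] <- comp
    }
    counts
}

#' Connected-components spectrum of a correlation matrix
#'
#' Sweeps `nThresholds` uniformly spaced thresholds between the minimum
#' and maximum off-diagonal absolute correlation; at each threshold the
#' thresholded matrix (edge where `|r| >` threshold, strict) is treated as
#' an undirected adjacency matrix and its connected components are
#' counted. Peaks of the resulting histogram at k = 1 indicate one network
#' of at least weak correlations; peaks at k = d indicate fully
#' uncorrelated measures; intermediate peaks indicate organization at
#' intermediate dimensionality.
#'
#' @param r symmetric correlation matrix with unit diagonal, or a
#'   \linkS4class{CorrelationResult}.
#' @param nThresholds number of threshold values (default 200).
#' @return A \linkS4class{ComponentSpectrum}. When all off-diagonal values
#'   are equal the sweep is degenerate: the spectrum is flagged and all
#'   histogram mass sits at the single resulting count.
#' @examples
#' r <- diag(5)
#' spectrumHistogram(connectedComponentsSpectrum(r))  # mass at k = 5
#' @export
connectedComponentsSpectrum <- function(r, nThresholds = 200L) {
    if (is(r, "CorrelationResult")) r <- r@r
    r <- as.matrix(r)
    d <- ncol(r)
    if (d < 2L) stop("at least 2 measures are required")
    if (!isSymmetric(unname(r), tol = 1e-8))
        stop("correlation matrix must be symmetric")
    a <- abs(r)
    ut <- which(upper.tri(a))
    w <- a[ut]
    degenerate <- length(unique(w)) == 1L
    thresholds <- if (degenerate) w[1L]
                  else seq(min(w), max(w), length.out = nThresholds)

    idx <- arrayInd(ut, dim(a))
    counts <- unionFindCounts(d, idx[, 1L], idx[, 2L], w, thresholds)

    tab <- tabulate(counts, nbins = d)
    hist <- tab / length(counts)
    names(hist) <- seq_len(d)
    new("ComponentSpectrum", thresholds = thresholds,
        nComponents = as.integer(counts), histogram = hist,
        counts = as.integer(tab), d = as.integer(d),
        degenerate = degenerate)
}

#' Spectrum robustness to randomly dropped measures
#'
#' Repeats the connected-components spectrum after removing random measure
#' subsets, profiling how the dimensionality histogram depends on specific
#' measures.
#'
#' @param r correlation matrix or \linkS4class{CorrelationResult}
#'   (d >= 3).
#' @param dropGrid numbers of measures to drop (each in 0..d-1).
#' @param nReps random subsets per drop level.
#' @param seed integer seed.
#' @param nThresholds passed to [connectedComponentsSpectrum()].
#' @return A list with one element per drop level: `dropped`, `spectra`
#'   (list of \linkS4class{ComponentSpectrum}) and `meanHistogram`
#'   (padded to length d).
#' @export
dropMeasureRobustness <- function(r, dropGrid, nReps = 10L, seed = 1L,
                                  nThresholds = 200L) {
    if (is(r, "CorrelationResult")) r <- r@r
    d <- ncol(r)
    if (d < 3L) stop("at least 3 measures are required")
    if (any(dropGrid < 0L) || any(dropGrid >= d))
        stop("drop levels must lie in [0, d - 1]")
    set.seed(as.integer(seed))
    lapply(dropGrid, function(nd) {
        reps <- if (nd == 0L) 1L else nReps
        spectra <- lapply(seq_len(reps), function(k) {
            keep <- if (nd == 0L) seq_len(d)
                    else sort(sample.int(d, d - nd))
            if (length(keep) == 1L) NULL
            else connectedComponentsSpectrum(r[keep, keep, drop = FALSE],
                                             nThresholds = nThresholds)
        })
        hists <- vapply(spectra, function(s) {
            h <- numeric(d)
            if (is.null(s)) h[1L] <- 1     # single remaining measure
            else h[seq_along(s@histogram)] <- s@histogram
            h
        }, numeric(d))
        list(dropped = nd, spectra = spectra,
             meanHistogram = setNames(rowMeans(hists), seq_len(d)))
    })
}
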