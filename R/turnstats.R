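## Higher-order turn statistics from event streams: handedness (direction
## bias), switchiness (serial dependence of direction), clumpiness
## (burstiness of timing), and discrete behavioral-state transition
## matrices.

#' @rdname handedness
#' @export
setMethod("handedness", "TurnSequence", function(x, ...) {
    if (length(x@times) < 1L) stop("at least one turn is required")
    mean(x@directions == "R")
})

binaryEntropy <- function(p) {
    p <- c(p, 1 - p)
    p <- p[p > 0]
    -sum(p * log2(p))
}

## Plug-in MI (bits) of the (n - 1) adjacent direction pairs.
adjacentPairMI <- function(dirs, correction = "none") {
    n <- length(dirs)
    x <- dirs[-n]; y <- dirs[-1L]
    joint <- table(factor(x, c("L", "R")), factor(y, c("L", "R"))) / (n - 1)
    px <- rowSums(joint); py <- colSums(joint)
    mi <- 0
    for (i in 1:2) for (j in 1:2) {
        if (joint[i, j] > 0)
            mi <- mi + joint[i, j] *
                log2(joint[i, j] / (px[i] * py[j]))
    }
    if (correction == "miller-madow") {
        nz <- function(p) sum(p > 0)
        mi <- mi + (nz(joint) - nz(px) - nz(py) + 1) / (2 * (n - 1) * log(2))
    }
    max(0, unname(mi))
}

#' @rdname switchiness
#' @param correction `"none"` (plug-in, default) or `"miller-madow"`.
#' @export
setMethod("switchiness", "TurnSequence",
    function(x, correction = c("none", "miller-madow"), ...) {
        correction <- match.arg(correction)
        if (length(x@times) < 2L) stop("at least two turns are required")
        adjacentPairMI(x@directions, correction)
    })

#' @rdname clumpiness
#' @export
setMethod("clumpiness", "TurnSequence", function(x, ...) {
    if (length(x@times) < 3L)
        stop("at least three turns (two intervals) are required")
    iti <- diff(x@times)
    mu <- mean(iti)
    if (mu <= 0) stop("mean inter-turn interval must be positive")
    sd(iti) / mu
})

#' Row-stochastic transition matrix of a discrete state sequence
#'
#' Counts adjacent (state i, state j) pairs and row-normalizes, giving the
#' probability that an individual in state i at one frame occupies state j
#' at the next. States never left (zero outgoing counts) give all-missing
#' rows, listed in `attr(result, "emptyRows")`.
#'
#' @param states integer vector of per-frame state labels in `1..K`.
#' @param K number of states (default `max(states)`).
#' @return K x K row-stochastic matrix.
#' @examples
#' transitionMatrix(c(1, 2, 1, 2), K = 2)
#' @export
transitionMatrix <- function(states, K = max(states)) {
    states <- as.integer(states)
    if (length(states) < 2L) stop("at least two frames are required")
    if (any(states < 1L | states > K))
        stop("state labels must lie in 1..K")
    n <- length(states)
    counts <- matrix(0, K, K)
    for (t in seq_len(n - 1L))
        counts[states[t], states[t + 1L]] <-
            counts[states[t], states[t + 1L]] + 1
    rs <- rowSums(counts)
    P <- counts / ifelse(rs == 0, NA_real_, rs)
    attr(P, "emptyRows") <- which(rs == 0)
    P
}

#' Turn statistics split by condition label
#'
#' Computes handedness, switchiness and clumpiness independently on each
#' condition's events (e.g., permissive vs restrictive temperature
#' blocks). A condition with fewer events than a statistic's minimum gives
#' `NA` for that cell, flagged in the `flagged` column.
#'
#' @param x a \linkS4class{TurnSequence} with condition labels.
#' @param ... ignored.
#' @return data.frame with one row per condition: `condition`, `nTurns`,
#'   `handedness`, `switchiness`, `clumpiness`, `flagged`.
#' @export
perConditionStats <- function(x, ...) {
    stopifnot(is(x, "TurnSequence"))
    if (!length(x@condition))
        stop("condition labels are required")
    conds <- unique(x@condition)
    out <- lapply(conds, function(cc) {
        sel <- x@condition == cc
        sub <- TurnSequence(x@times[sel], x@directions[sel])
        safely <- function(f, minN) {
            if (sum(sel) < minN) NA_real_ else f(sub)
        }
        h <- safely(handedness, 1L)
        s <- safely(switchiness, 2L)
        cl <- safely(clumpiness, 3L)
        data.frame(condition = cc, nTurns = sum(sel), handedness = h,
                   switchiness = s, clumpiness = cl,
                   flagged = anyNA(c(h, s, cl)))
    })
    do.call(rbind, out)
}
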