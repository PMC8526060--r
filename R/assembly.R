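## Assembly: batch-wise standardization and cross-experiment merging of
## behavioral matrices.
##
## The normalization pipeline mirrors how serially phenotyped cohorts are
## combined: measures are z-scored within each batch (removing per-batch
## mean/variance shifts), matrices from separate experiments are matched on
## (assay, measure) keys -- with day of testing ignored except for circadian
## measures, which recur daily -- and the merged matrix is re-z-scored by
## measure.

zscoreVector <- function(x) {
    ok <- !is.na(x)
    if (sum(ok) == 0L) return(list(x = x, constant = FALSE))
    s <- sd(x[ok])
    if (sum(ok) < 2L || !is.finite(s) || s == 0) {
        x[ok] <- 0          # constant block: map to the (batch) mean
        return(list(x = x, constant = TRUE))
    }
    x[ok] <- (x[ok] - mean(x[ok])) / s
    list(x = x, constant = FALSE)
}

#' Z-score a MeasureMatrix within each batch
#'
#' Standardizes every measure to mean 0 and sample (n-1) standard deviation
#' 1 within each batch, over non-missing entries. Missing entries stay
#' missing. A constant (zero-variance) batch-by-measure block is set to 0
#' (its batch mean) with a warning rather than producing divisions by zero.
#'
#' @param m a \linkS4class{MeasureMatrix}.
#' @return A \linkS4class{MeasureMatrix} with standardized values.
#' @examples
#' m <- MeasureMatrix(matrix(1:6, 3, 2), batch = "b1")
#' measureValues(zscoreByBatch(m))[, 1]   # -1 0 1
#' @export
zscoreByBatch <- function(m) {
    stopifnot(is(m, "MeasureMatrix"))
    v <- m@values
    nConst <- 0L
    for (b in unique(m@batch)) {
        rows <- which(m@batch == b)
        for (j in seq_len(ncol(v))) {
            z <- zscoreVector(v[rows, j])
            v[rows, j] <- z$x
            if (z$constant && any(!is.na(z$x))) nConst <- nConst + 1L
        }
    }
    if (nConst > 0L)
        warning(sprintf("%d constant batch x measure block(s) set to 0",
                        nConst))
    initialize(m, values = v)
}

#' Z-score a MeasureMatrix by measure over all individuals
#'
#' @param m a \linkS4class{MeasureMatrix}.
#' @return A \linkS4class{MeasureMatrix} with each column standardized to
#'   mean 0 and sample SD 1 over its non-missing entries.
#' @export
zscoreByMeasure <- function(m) {
    stopifnot(is(m, "MeasureMatrix"))
    v <- m@values
    nConst <- 0L
    for (j in seq_len(ncol(v))) {
        z <- zscoreVector(v[, j])
        v[, j] <- z$x
        if (z$constant && any(!is.na(z$x))) nConst <- nConst + 1L
    }
    if (nConst > 0L)
        warning(sprintf("%d constant measure(s) set to 0", nConst))
    initialize(m, values = v)
}

## Merge key: (assay, measure, day) for circadian-class assays, day dropped
## otherwise.
mergeKey <- function(info, circadianAssays) {
    useDay <- info$assay %in% circadianAssays & !is.na(info$day)
    key <- paste(info$assay, info$measure, sep = ".")
    key[useDay] <- paste0(key[useDay], ".day", info$day[useDay])
    key
}

#' Match measures and concatenate two behavioral matrices
#'
#' Stacks the individuals of two (batch-z-scored) matrices and aligns their
#' measures on (assay, measure) keys. Day of testing is ignored when
#' matching -- assay order is typically randomized between experiments --
#' except for assays named in `circadianAssays`, whose measures recur every
#' day and are matched by day. Cells with no matching measure in the other
#' matrix are missing. The merged matrix is then z-scored by measure over
#' all individuals.
#'
#' A merge report (matched/unmatched keys, inserted-missing counts) is
#' stored in `metadata(result)$mergeReport`.
#'
#' @param a,b \linkS4class{MeasureMatrix} objects with disjoint individual
#'   ids (ids are suffixed to disambiguate collisions).
#' @param circadianAssays assay names whose measures are matched by day.
#' @param rescale re-z-score the merged matrix by measure (default TRUE).
#' @return A merged \linkS4class{MeasureMatrix}.
#' @export
matchAndConcatenate <- function(a, b, circadianAssays = "circadian",
                                rescale = TRUE) {
    stopifnot(is(a, "MeasureMatrix"), is(b, "MeasureMatrix"))
    keyA <- mergeKey(a@measureInfo, circadianAssays)
    keyB <- mergeKey(b@measureInfo, circadianAssays)
    if (anyDuplicated(keyA))
        stop("duplicate measure keys in first matrix: ",
             paste(unique(keyA[duplicated(keyA)]), collapse = ", "))
    if (anyDuplicated(keyB))
        stop("duplicate measure keys in second matrix: ",
             paste(unique(keyB[duplicated(keyB)]), collapse = ", "))

    allKeys <- union(keyA, keyB)
    nA <- nrow(a@values); nB <- nrow(b@values)
    out <- matrix(NA_real_, nA + nB, length(allKeys),
                  dimnames = list(NULL, allKeys))
    out[seq_len(nA), match(keyA, allKeys)] <- a@values
    out[nA + seq_len(nB), match(keyB, allKeys)] <- b@values

    ids <- c(rownames(a@values), rownames(b@values))
    if (anyDuplicated(ids))
        ids <- make.unique(ids, sep = "_")
    rownames(out) <- ids

    # Per-measure metadata: prefer a's metadata where keys overlap.
    idxA <- match(allKeys, keyA)
    idxB <- match(allKeys, keyB)
    takeA <- !is.na(idxA)
    info <- DataFrame(
        assay = ifelse(takeA, a@measureInfo$assay[idxA],
                       b@measureInfo$assay[idxB]),
        measure = ifelse(takeA, a@measureInfo$measure[idxA],
                         b@measureInfo$measure[idxB]),
        day = ifelse(takeA, a@measureInfo$day[idxA],
                     b@measureInfo$day[idxB]),
        group = ifelse(takeA, a@measureInfo$group[idxA],
                       b@measureInfo$group[idxB]))
    # Day loses its identity role for matched non-circadian measures.
    info$day[!(info$assay %in% circadianAssays)] <- NA_integer_
    rownames(info) <- allKeys

    merged <- new("MeasureMatrix", values = out,
                  batch = c(a@batch, b@batch), measureInfo = info)
    metadata(merged)$mergeReport <- list(
        matchedKeys = intersect(keyA, keyB),
        onlyFirst = setdiff(keyA, keyB),
        onlySecond = setdiff(keyB, keyA),
        insertedMissing = sum(is.na(out)) -
            (sum(is.na(a@values)) + sum(is.na(b@values))))
    if (rescale) merged <- zscoreByMeasure(merged)
    merged
}

#' Write the merge report of a merged MeasureMatrix as JSON
#'
#' @param m a \linkS4class{MeasureMatrix} produced by
#'   [matchAndConcatenate()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeMergeReport <- function(m, file) {
    rep <- metadata(m)$mergeReport
    if (is.null(rep)) stop("no merge report attached to this matrix")
    jsonlite::write_json(rep, file, auto_unbox = TRUE, pretty = TRUE)
    invisible(file)
}
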