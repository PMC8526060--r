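## Central S4 containers. Conventions: individuals index rows of behavioral
## matrices; measures index columns; measure metadata rides along in a
## DataFrame with one row per measure.

#' MeasureMatrix: individuals-by-measures behavioral data
#'
#' Holds an individuals x measures numeric matrix (missing entries allowed),
#' per-individual batch labels, and per-measure metadata (assay, measure
#' name, day of testing, a-priori group). The `metadata()` list (from
#' \linkS4class{Annotated}) carries provenance such as simulation ground
#' truth or merge reports.
#'
#' @slot values numeric matrix, individuals x measures; `NA` marks missing.
#' @slot batch character vector, one batch label per individual.
#' @slot measureInfo \linkS4class{DataFrame} with columns `assay`, `measure`,
#'   `day` (integer, `NA` when day is not part of the measure identity) and
#'   `group` (a-priori group, `NA` for ungrouped measures).
#'
#' @seealso [MeasureMatrix()] for construction, [zscoreByBatch()],
#'   [matchAndConcatenate()], [medianAlsImpute()], [distill()]
#' @export
setClass("MeasureMatrix",
    contains = "Annotated",
    slots = c(values = "matrix", batch = "character", measureInfo = "DataFrame"))

setValidity("MeasureMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be a numeric matrix")
    if (length(object@batch) != nrow(v))
        msg <- c(msg, "one batch label is required per individual (row)")
    if (anyNA(object@batch))
        msg <- c(msg, "batch labels must not be NA")
    if (nrow(object@measureInfo) != ncol(v))
        msg <- c(msg, "measureInfo must have one row per measure (column)")
    if (!all(c("assay", "measure", "day", "group") %in%
             colnames(object@measureInfo)))
        msg <- c(msg, "measureInfo needs columns assay, measure, day, group")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        msg <- c(msg, "individual ids (rownames) must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Construct a MeasureMatrix
#'
#' @param values numeric matrix, individuals x measures. Rownames are taken
#'   as individual ids (generated if absent).
#' @param batch character vector of per-individual batch labels (recycled if
#'   length 1).
#' @param assay,measure character vectors, one entry per measure.
#' @param day integer vector per measure; `NA` where day is not part of the
#'   measure identity (non-circadian assays).
#' @param group a-priori group label per measure; `NA` for ungrouped.
#' @return A \linkS4class{MeasureMatrix}.
#' @examples
#' m <- MeasureMatrix(matrix(rnorm(12), 4, 3), batch = "b1",
#'                    assay = "ymaze", measure = c("speed", "bias", "turns"))
#' nMeasures(m)
#' @export
MeasureMatrix <- function(values, batch = "batch1",
                          assay = "assay", measure = NULL,
                          day = NA_integer_, group = NA_character_) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("ind_%03d", seq_len(nrow(values)))
    d <- ncol(values)
    if (is.null(measure)) {
        measure <- if (!is.null(colnames(values))) colnames(values)
                   else sprintf("m%02d", seq_len(d))
    }
    info <- DataFrame(assay = rep_len(as.character(assay), d),
                      measure = rep_len(as.character(measure), d),
                      day = rep_len(as.integer(day), d),
                      group = rep_len(as.character(group), d))
    colnames(values) <- measureKeyString(info)
    rownames(info) <- colnames(values)
    new("MeasureMatrix", values = values,
        batch = rep_len(as.character(batch), nrow(values)),
        measureInfo = info)
}

## Canonical measure-key string: assay.measure, with ".dayN" appended only
## when the day participates in the measure identity.
measureKeyString <- function(info) {
    key <- paste(info$assay, info$measure, sep = ".")
    hasDay <- !is.na(info$day)
    key[hasDay] <- paste0(key[hasDay], ".day", info$day[hasDay])
    key
}

#' PCSelection: shuffle-calibrated PC retention for one measure group
#'
#' @slot group group name.
#' @slot nMeasures number of measures in the group.
#' @slot nSignificant number of retained principal components.
#' @slot loadings measures x retained-PC loading matrix.
#' @slot varianceExplained fraction of variance per PC rank (all ranks).
#' @slot nullLower,nullUpper per-rank confidence bounds of the
#'   variance-explained null from column-shuffled matrices.
#' @export
setClass("PCSelection",
    slots = c(group = "character", nMeasures = "integer",
              nSignificant = "integer", loadings = "matrix",
              varianceExplained = "numeric",
              nullLower = "numeric", nullUpper = "numeric"))

setValidity("PCSelection", function(object) {
    if (object@nSignificant < 1L || object@nSignificant > object@nMeasures)
        return("nSignificant must lie in [1, nMeasures]")
    if (sum(object@varianceExplained[seq_len(object@nSignificant)]) > 1 + 1e-8)
        return("variance explained by retained PCs cannot exceed 1")
    TRUE
})

#' DistilledMatrix: group submatrices replaced by significant PC scores
#'
#' @slot values individuals x retained-column score matrix (re-z-scored).
#' @slot provenance \linkS4class{DataFrame} with one row per column:
#'   `group`, `pc` (PC rank, `NA` for pass-through measures) and `source`
#'   (`"pc"` or `"measure"`).
#' @slot selections list of \linkS4class{PCSelection}, one per group.
#' @export
setClass("DistilledMatrix",
    contains = "Annotated",
    slots = c(values = "matrix", provenance = "DataFrame",
              selections = "list"))

setValidity("DistilledMatrix", function(object) {
    if (nrow(object@provenance) != ncol(object@values))
        return("provenance must describe every column")
    TRUE
})

#' ImputationResult: median-aggregated ALS completion of a MeasureMatrix
#'
#' @slot completed individuals x measures matrix with no missing values;
#'   observed entries agree exactly with the input.
#' @slot rank rank of the low-rank factor model used.
#' @slot nRepetitions number of ALS repetitions aggregated by the median.
#' @slot seeds per-repetition random seeds.
#' @slot convergence \linkS4class{DataFrame} with per-repetition
#'   `iterations` and final observed-entry `residual`.
#' @export
setClass("ImputationResult",
    slots = c(completed = "matrix", rank = "integer",
              nRepetitions = "integer", seeds = "integer",
              convergence = "DataFrame"))

setValidity("ImputationResult", function(object) {
    if (anyNA(object@completed))
        return("completed matrix must not contain missing values")
    TRUE
})

#' CorrelationResult: pairwise Spearman correlation matrix with p-values
#'
#' @slot r d x d symmetric Spearman rank correlation matrix.
#' @slot p d x d two-tailed p-value matrix from the t-transform of r.
#' @slot n d x d matrix of paired-observation counts.
#' @export
setClass("CorrelationResult",
    slots = c(r = "matrix", p = "matrix", n = "matrix"))

setValidity("CorrelationResult", function(object) {
    r <- object@r
    if (!isTRUE(all.equal(dim(r), dim(object@p))) ||
        !isTRUE(all.equal(dim(r), dim(object@n))))
        return("r, p and n must share dimensions")
    if (any(abs(r) > 1 + 1e-8, na.rm = TRUE))
        return("|r| must not exceed 1")
    pv <- object@p
    if (any(pv < -1e-12 | pv > 1 + 1e-12, na.rm = TRUE))
        return("p-values must lie in [0, 1]")
    TRUE
})

#' FDRCurve: bootstrap kernel-density false discovery rate estimate
#'
#' The FDR at a threshold alpha is the ratio of the mean null (shuffled)
#' p-value density to the mean observed p-value density, each averaged over
#' bootstrap resamples of individuals.
#'
#' @slot alphaGrid p-value grid on \[0, 1\].
#' @slot fdr estimated FDR at each grid point.
#' @slot observedDensity,nullDensity mean kernel density estimates of the
#'   observed and column-shuffled p-value distributions.
#' @slot alpha the working significance threshold.
#' @slot fdrAtAlpha FDR evaluated at `alpha`.
#' @slot nSignificant number of unique measure pairs with p < alpha on the
#'   unresampled matrix.
#' @export
setClass("FDRCurve",
    slots = c(alphaGrid = "numeric", fdr = "numeric",
              observedDensity = "numeric", nullDensity = "numeric",
              alpha = "numeric", fdrAtAlpha = "numeric",
              nSignificant = "integer"))

#' ComponentSpectrum: dimensionality profile of a correlation matrix
#'
#' Sweeps thresholds over the off-diagonal absolute correlations; at each
#' threshold the matrix is read as an adjacency matrix (edge where |r| >
#' threshold) and the number of connected components is recorded. The
#' histogram gives, for each possible component count k in 1..d, the
#' fraction of thresholds yielding k components.
#'
#' @slot thresholds swept threshold values.
#' @slot nComponents component count at each threshold.
#' @slot histogram named numeric of length d; fraction of thresholds per
#'   component count (sums to 1).
#' @slot counts raw threshold counts per component count.
#' @slot d matrix dimensionality.
#' @slot degenerate TRUE when all off-diagonal values were equal and the
#'   sweep collapsed to a single threshold.
#' @export
setClass("ComponentSpectrum",
    slots = c(thresholds = "numeric", nComponents = "integer",
              histogram = "numeric", counts = "integer",
              d = "integer", degenerate = "logical"))

setValidity("ComponentSpectrum", function(object) {
    if (abs(sum(object@histogram) - 1) > 1e-8)
        return("histogram must sum to 1")
    k <- object@nComponents
    if (any(k < 1L) || any(k > object@d))
        return("component counts must lie in [1, d]")
    if (is.unsorted(k))
        return("component counts must be non-decreasing in threshold")
    TRUE
})

#' TurnSequence: timed binary-choice events for one individual
#'
#' @slot times strictly increasing event times (seconds).
#' @slot directions per-event direction, `"R"` or `"L"`.
#' @slot condition optional per-event condition label (e.g., temperature
#'   block); length zero when absent.
#' @export
setClass("TurnSequence",
    slots = c(times = "numeric", directions = "character",
              condition = "character"))

setValidity("TurnSequence", function(object) {
    if (length(object@times) != length(object@directions))
        return("times and directions must have equal length")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
        return("times must be strictly increasing")
    if (!all(object@directions %in% c("L", "R")))
        return("directions must be 'L' or 'R'")
    if (length(object@condition) &&
        length(object@condition) != length(object@times))
        return("condition labels, when present, must match event count")
    TRUE
})

#' Construct a TurnSequence
#'
#' @param times strictly increasing event times in seconds.
#' @param directions character vector of `"R"`/`"L"` per event.
#' @param condition optional per-event condition label.
#' @return A \linkS4class{TurnSequence}.
#' @examples
#' ts <- TurnSequence(cumsum(rexp(10)), rep(c("R", "L"), 5))
#' handedness(ts)
#' @export
TurnSequence <- function(times, directions, condition = character()) {
    new("TurnSequence", times = as.numeric(times),
        directions = as.character(directions),
        condition = as.character(condition))
}

#' ExpressionDataset: gene-by-individual counts with normalized expression
#'
#' A \linkS4class{SummarizedExperiment} whose `"counts"` assay holds
#' non-negative integer read counts (genes x individuals). After
#' [filterAndNormalize()] the object additionally carries `"rpm"` (reads
#' per million) and `"normalized"` (quantile-normalized RPM) assays.
#'
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("an ExpressionDataset requires a 'counts' assay")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0, na.rm = TRUE))
        return("counts must be non-negative")
    TRUE
})

#' Construct an ExpressionDataset from a count matrix
#'
#' @param counts non-negative gene x individual count matrix with gene ids
#'   as rownames and individual ids as colnames.
#' @param ... further assays (e.g., `normalized`), matrices conformable
#'   with `counts`.
#' @return An \linkS4class{ExpressionDataset}.
#' @export
ExpressionDataset <- function(counts, ...) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("gene_%05d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("ind_%03d", seq_len(ncol(counts)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = c(list(counts = counts), list(...)))
    new("ExpressionDataset", se)
}

#' ModelScreenResult: the single-gene linear-model screen
#'
#' One ordinary-least-squares fit per (gene, behavior) pair of behavior on
#' normalized expression.
#'
#' @slot table \linkS4class{DataFrame} with columns `gene`, `behavior`,
#'   `slope`, `r2`, `p` and `flagged` (TRUE where the model was skipped for
#'   zero variance).
#' @slot alpha per-model significance threshold used for gene lists.
#' @export
setClass("ModelScreenResult",
    slots = c(table = "DataFrame", alpha = "numeric"))
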