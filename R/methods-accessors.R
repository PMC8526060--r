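## Accessor and show methods.

#' @rdname MeasureMatrix-class
#' @export
setMethod("measureValues", "MeasureMatrix", function(x) x@values)

#' @rdname MeasureMatrix-class
#' @export
setMethod("batchLabels", "MeasureMatrix", function(x) x@batch)

#' @rdname MeasureMatrix-class
#' @export
setMethod("measureInfo", "MeasureMatrix", function(x) x@measureInfo)

#' @rdname MeasureMatrix-class
#' @export
setMethod("groupLabels", "MeasureMatrix", function(x) x@measureInfo$group)

#' @rdname MeasureMatrix-class
#' @param value replacement group labels (one per measure).
#' @export
setReplaceMethod("groupLabels", "MeasureMatrix", function(x, value) {
    x@measureInfo$group <- rep_len(as.character(value), nMeasures(x))
    x
})

#' @rdname MeasureMatrix-class
#' @export
setMethod("nIndividuals", "MeasureMatrix", function(x) nrow(x@values))

#' @rdname MeasureMatrix-class
#' @export
setMethod("nMeasures", "MeasureMatrix", function(x) ncol(x@values))

#' @rdname MeasureMatrix-class
#' @export
setMethod("individualIds", "MeasureMatrix", function(x) rownames(x@values))

#' @rdname MeasureMatrix-class
#' @export
setMethod("measureKeys", "MeasureMatrix", function(x) colnames(x@values))

#' @rdname MeasureMatrix-class
#' @export
setMethod("dim", "MeasureMatrix", function(x) dim(x@values))

#' Subset a MeasureMatrix by individuals (i) and measures (j)
#'
#' @param x a \linkS4class{MeasureMatrix}.
#' @param i,j row (individual) and column (measure) indices.
#' @param drop ignored; subsetting always returns a MeasureMatrix.
#' @param ... ignored.
#' @export
setMethod("[", "MeasureMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@values))
    if (missing(j)) j <- seq_len(ncol(x@values))
    initialize(x, values = x@values[i, j, drop = FALSE],
               batch = x@batch[i],
               measureInfo = x@measureInfo[j, , drop = FALSE])
})

setMethod("show", "MeasureMatrix", function(object) {
    v <- object@values
    fracNA <- if (length(v)) mean(is.na(v)) else 0
    cat(sprintf("MeasureMatrix: %d individuals x %d measures\n",
                nrow(v), ncol(v)))
    cat(sprintf("  batches: %d | missing: %.1f%% | groups: %d\n",
                length(unique(object@batch)), 100 * fracNA,
                length(unique(stats::na.omit(object@measureInfo$group)))))
    keys <- colnames(v)
    cat("  measures: ", paste(head(keys, 4), collapse = ", "),
        if (length(keys) > 4) ", ..." else "", "\n", sep = "")
})

#' @rdname DistilledMatrix-class
#' @export
setMethod("measureValues", "DistilledMatrix", function(x) x@values)

#' @rdname DistilledMatrix-class
#' @export
setMethod("provenance", "DistilledMatrix", function(x) x@provenance)

#' @rdname DistilledMatrix-class
#' @export
setMethod("pcSelections", "DistilledMatrix", function(x) x@selections)

#' @rdname DistilledMatrix-class
#' @export
setMethod("nIndividuals", "DistilledMatrix", function(x) nrow(x@values))

#' @rdname DistilledMatrix-class
#' @export
setMethod("nMeasures", "DistilledMatrix", function(x) ncol(x@values))

setMethod("show", "DistilledMatrix", function(object) {
    cat(sprintf("DistilledMatrix: %d individuals x %d columns\n",
                nrow(object@values), ncol(object@values)))
    src <- object@provenance$source
    cat(sprintf("  %d group-PC scores from %d groups, %d pass-through measures\n",
                sum(src == "pc"), length(object@selections),
                sum(src == "measure")))
})

#' @rdname PCSelection-class
#' @export
setMethod("nSignificant", "PCSelection", function(x) x@nSignificant)

#' @rdname PCSelection-class
#' @export
setMethod("pcLoadings", "PCSelection", function(x) x@loadings)

#' @rdname PCSelection-class
#' @export
setMethod("varianceExplained", "PCSelection", function(x) x@varianceExplained)

setMethod("show", "PCSelection", function(object) {
    cat(sprintf("PCSelection '%s': %d of %d PCs retained\n", object@group,
                object@nSignificant, object@nMeasures))
    cat(sprintf("  variance explained (retained): %s\n",
                paste(sprintf("%.3f",
                      object@varianceExplained[seq_len(object@nSignificant)]),
                      collapse = " ")))
})

#' @rdname ImputationResult-class
#' @export
setMethod("completedMatrix", "ImputationResult", function(x) x@completed)

#' @rdname ImputationResult-class
#' @export
setMethod("convergenceInfo", "ImputationResult", function(x) x@convergence)

setMethod("show", "ImputationResult", function(object) {
    cat(sprintf("ImputationResult: %d x %d, rank %d, median of %d ALS runs\n",
                nrow(object@completed), ncol(object@completed),
                object@rank, object@nRepetitions))
})

#' @rdname CorrelationResult-class
#' @export
setMethod("corMatrix", "CorrelationResult", function(x) x@r)

#' @rdname CorrelationResult-class
#' @export
setMethod("pMatrix", "CorrelationResult", function(x) x@p)

#' @rdname CorrelationResult-class
#' @export
setMethod("nPairs", "CorrelationResult", function(x) x@n)

setMethod("show", "CorrelationResult", function(object) {
    d <- ncol(object@r)
    off <- object@r[upper.tri(object@r)]
    cat(sprintf("CorrelationResult: %d x %d Spearman matrix\n", d, d))
    cat(sprintf("  off-diagonal |r|: median %.3f, max %.3f\n",
                median(abs(off), na.rm = TRUE), max(abs(off), na.rm = TRUE)))
})

#' @rdname ComponentSpectrum-class
#' @export
setMethod("thresholds", "ComponentSpectrum", function(x) x@thresholds)

#' @rdname ComponentSpectrum-class
#' @export
setMethod("componentCounts", "ComponentSpectrum", function(x) x@nComponents)

#' @rdname ComponentSpectrum-class
#' @export
setMethod("spectrumHistogram", "ComponentSpectrum", function(x) x@histogram)

setMethod("show", "ComponentSpectrum", function(object) {
    cat(sprintf("ComponentSpectrum: d = %d, %d thresholds%s\n", object@d,
                length(object@thresholds),
                if (object@degenerate) " (degenerate sweep)" else ""))
    top <- sort(object@histogram[object@histogram > 0], decreasing = TRUE)
    cat("  histogram peaks at k = ",
        paste(head(names(top), 3), collapse = ", "), "\n", sep = "")
})

#' @rdname TurnSequence-class
#' @export
setMethod("turnTimes", "TurnSequence", function(x) x@times)

#' @rdname TurnSequence-class
#' @export
setMethod("turnDirections", "TurnSequence", function(x) x@directions)

#' @rdname TurnSequence-class
#' @export
setMethod("turnConditions", "TurnSequence", function(x) x@condition)

#' @rdname TurnSequence-class
#' @export
setMethod("length", "TurnSequence", function(x) length(x@times))

setMethod("show", "TurnSequence", function(object) {
    cat(sprintf("TurnSequence: %d turns over %.1f s, right fraction %.2f\n",
                length(object@times), diff(range(object@times)),
                mean(object@directions == "R")))
})

#' @rdname ModelScreenResult-class
#' @export
setMethod("screenTable", "ModelScreenResult", function(x) x@table)

#' @rdname ModelScreenResult-class
#' @param behavior behavior key to extract significant genes for.
#' @export
setMethod("significantGenes", "ModelScreenResult",
    function(x, behavior, ...) {
        tab <- x@table
        sel <- tab$behavior == behavior & !tab$flagged & tab$p < x@alpha
        as.character(tab$gene[sel])
    })

setMethod("show", "ModelScreenResult", function(object) {
    tab <- object@table
    cat(sprintf("ModelScreenResult: %d models (%d genes x %d behaviors)\n",
                nrow(tab), length(unique(tab$gene)),
                length(unique(tab$behavior))))
    ok <- !tab$flagged
    cat(sprintf("  significant at p < %.2g: %d (%.1f%%)\n", object@alpha,
                sum(tab$p[ok] < object@alpha, na.rm = TRUE),
                100 * mean(tab$p[ok] < object@alpha, na.rm = TRUE)))
})

setMethod("show", "FDRCurve", function(object) {
    cat(sprintf("FDRCurve: FDR(%.2g) = %.3f, %d significant pairs\n",
                object@alpha, object@fdrAtAlpha, object@nSignificant))
})
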