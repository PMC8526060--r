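## Generics and accessors. Slot access from user code goes through these.

#' @rdname MeasureMatrix-class
#' @param x,object a \linkS4class{MeasureMatrix} or
#'   \linkS4class{DistilledMatrix}.
#' @export
setGeneric("measureValues", function(x) standardGeneric("measureValues"))

#' @rdname MeasureMatrix-class
#' @export
setGeneric("batchLabels", function(x) standardGeneric("batchLabels"))

#' @rdname MeasureMatrix-class
#' @export
setGeneric("measureInfo", function(x) standardGeneric("measureInfo"))

#' @rdname MeasureMatrix-class
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname MeasureMatrix-class
#' @export
setGeneric("groupLabels<-", function(x, value) standardGeneric("groupLabels<-"))

#' @rdname MeasureMatrix-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname MeasureMatrix-class
#' @export
setGeneric("nMeasures", function(x) standardGeneric("nMeasures"))

#' @rdname MeasureMatrix-class
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname MeasureMatrix-class
#' @export
setGeneric("measureKeys", function(x) standardGeneric("measureKeys"))

#' @rdname DistilledMatrix-class
#' @param x a \linkS4class{DistilledMatrix}.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname DistilledMatrix-class
#' @export
setGeneric("pcSelections", function(x) standardGeneric("pcSelections"))

#' @rdname PCSelection-class
#' @param x a \linkS4class{PCSelection}.
#' @export
setGeneric("nSignificant", function(x) standardGeneric("nSignificant"))

#' @rdname PCSelection-class
#' @export
setGeneric("pcLoadings", function(x) standardGeneric("pcLoadings"))

#' @rdname PCSelection-class
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @rdname ImputationResult-class
#' @param x an \linkS4class{ImputationResult}.
#' @export
setGeneric("completedMatrix", function(x) standardGeneric("completedMatrix"))

#' @rdname ImputationResult-class
#' @export
setGeneric("convergenceInfo", function(x) standardGeneric("convergenceInfo"))

#' @rdname CorrelationResult-class
#' @param x a \linkS4class{CorrelationResult}.
#' @export
setGeneric("corMatrix", function(x) standardGeneric("corMatrix"))

#' @rdname CorrelationResult-class
#' @export
setGeneric("pMatrix", function(x) standardGeneric("pMatrix"))

#' @rdname CorrelationResult-class
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname ComponentSpectrum-class
#' @param x a \linkS4class{ComponentSpectrum}.
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname ComponentSpectrum-class
#' @export
setGeneric("componentCounts", function(x) standardGeneric("componentCounts"))

#' @rdname ComponentSpectrum-class
#' @export
setGeneric("spectrumHistogram", function(x) standardGeneric("spectrumHistogram"))

#' @rdname TurnSequence-class
#' @param x a \linkS4class{TurnSequence}.
#' @export
setGeneric("turnTimes", function(x) standardGeneric("turnTimes"))

#' @rdname TurnSequence-class
#' @export
setGeneric("turnDirections", function(x) standardGeneric("turnDirections"))

#' @rdname TurnSequence-class
#' @export
setGeneric("turnConditions", function(x) standardGeneric("turnConditions"))

#' Handedness: fraction of right turns
#'
#' @param x a \linkS4class{TurnSequence}.
#' @param ... passed to methods.
#' @return Numeric in \[0, 1\].
#' @export
setGeneric("handedness", function(x, ...) standardGeneric("handedness"))

#' Switchiness: mutual information of consecutive turn directions
#'
#' Plug-in mutual information (bits) between each turn direction and the
#' next, estimated from the empirical joint distribution of adjacent pairs.
#' Perfect alternation gives 1 bit; independent turns give 0.
#'
#' @param x a \linkS4class{TurnSequence}.
#' @param ... passed to methods (`correction = "miller-madow"` applies the
#'   Miller-Madow small-sample bias correction).
#' @return Mutual information in bits.
#' @export
setGeneric("switchiness", function(x, ...) standardGeneric("switchiness"))

#' Clumpiness: coefficient of variation of inter-turn intervals
#'
#' Sample standard deviation over mean of the successive inter-event
#' intervals; 0 for perfectly periodic events, 1 for a Poisson process,
#' above 1 for bursty timing.
#'
#' @param x a \linkS4class{TurnSequence}.
#' @param ... passed to methods.
#' @return Non-negative numeric.
#' @export
setGeneric("clumpiness", function(x, ...) standardGeneric("clumpiness"))

#' @rdname ModelScreenResult-class
#' @param x a \linkS4class{ModelScreenResult}.
#' @export
setGeneric("screenTable", function(x) standardGeneric("screenTable"))

#' Significant predictive genes for one behavior
#'
#' @param x a \linkS4class{ModelScreenResult}.
#' @param behavior behavior (measure key) name.
#' @param ... passed to methods.
#' @return Character vector of gene ids with model p below the screen's
#'   alpha.
#' @export
setGeneric("significantGenes",
           function(x, behavior, ...) standardGeneric("significantGenes"))
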