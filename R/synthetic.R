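## Synthetic-data generators with known ground truth. Every downstream
## stage of the pipeline is validated against data produced here:
## block-factor behavioral matrices with batch effects and missingness,
## Markov turn-event streams, and Poisson count matrices with a registry
## of genes coupled to behaviors.

#' Specify the ground truth of a synthetic behavioral matrix
#'
#' Measures are generated from a latent-factor model: each a-priori group
#' carries its own latent factors, measures load on one factor each
#' (round-robin within the group), and independent noise is added so each
#' measure has unit variance on the latent scale. Optional cross-group
#' edges plant target correlations between specific measures of different
#' groups. Per-batch mean shifts and variance scales emulate batch
#' effects; entries are then masked missing.
#'
#' @param nIndividuals number of individuals.
#' @param groups data.frame with columns `group`, `nMeasures`, `nFactors`,
#'   `loading` (loading of each measure on its factor, in \[0, 1)).
#' @param batches data.frame with columns `batch`, `size`, `meanShift`,
#'   `varScale`; sizes must sum to `nIndividuals`. Default: one neutral
#'   batch.
#' @param crossGroupEdges optional data.frame with columns `i`, `j`
#'   (global measure indices) and `r` (target correlation).
#' @param missingRate missing-completely-at-random rate in \[0, 1\]
#'   (default 0.23, a typical missingness level for serial multi-assay
#'   phenotyping).
#' @param noiseSd unique-noise SD; default `sqrt(1 - loading^2)` per group
#'   so measures have unit latent-scale variance.
#' @param missingMechanism `"mcar"` (default) or `"activity"`, where the
#'   missingness probability of a row increases as its first measure
#'   (an activity proxy) decreases -- for robustness studies only.
#' @param seed integer seed.
#' @return A classed list (`MeasureTruthSpec`).
#' @export
measureTruthSpec <- function(nIndividuals, groups,
                             batches = NULL, crossGroupEdges = NULL,
                             missingRate = 0.23, noiseSd = NULL,
                             missingMechanism = c("mcar", "activity"),
                             seed = 1L) {
    missingMechanism <- match.arg(missingMechanism)
    if (is.null(batches))
        batches <- data.frame(batch = "batch1", size = nIndividuals,
                              meanShift = 0, varScale = 1)
    stopifnot(all(c("group", "nMeasures", "nFactors", "loading") %in%
                  names(groups)),
              all(c("batch", "size", "meanShift", "varScale") %in%
                  names(batches)))
    if (sum(batches$size) != nIndividuals)
        stop("batch sizes must sum to nIndividuals")
    if (any(batches$size < 1L)) stop("zero-size batch")
    if (any(groups$nMeasures < 1L) || any(groups$nFactors < 1L))
        stop("zero-size group or factor count")
    if (any(groups$nFactors > groups$nMeasures))
        stop("a group cannot have more factors than measures")
    if (missingRate < 0 || missingRate > 1)
        stop("missingRate must lie in [0, 1]")
    if (any(groups$loading < 0)) stop("loading must be non-negative")
    structure(list(nIndividuals = as.integer(nIndividuals),
                   groups = groups, batches = batches,
                   crossGroupEdges = crossGroupEdges,
                   missingRate = missingRate, noiseSd = noiseSd,
                   missingMechanism = missingMechanism,
                   seed = as.integer(seed)),
              class = "MeasureTruthSpec")
}

## Target correlation matrix implied by a MeasureTruthSpec (latent scale,
## before batch effects).
truthCorrelation <- function(spec) {
    g <- spec$groups
    d <- sum(g$nMeasures)
    factorOf <- integer(d)     # global factor index per measure
    groupOf <- character(d)
    load <- numeric(d)
    pos <- 0L; fpos <- 0L
    for (k in seq_len(nrow(g))) {
        idx <- pos + seq_len(g$nMeasures[k])
        factorOf[idx] <- fpos + ((seq_along(idx) - 1L) %% g$nFactors[k]) + 1L
        groupOf[idx] <- g$group[k]
        load[idx] <- g$loading[k]
        pos <- pos + g$nMeasures[k]
        fpos <- fpos + g$nFactors[k]
    }
    noise <- if (is.null(spec$noiseSd)) sqrt(pmax(1 - load^2, 1e-6))
             else rep_len(spec$noiseSd, d)
    tot <- sqrt(load^2 + noise^2)
    R <- diag(d)
    for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
        if (factorOf[i] == factorOf[j])
            R[i, j] <- R[j, i] <- load[i] * load[j] / (tot[i] * tot[j])
    }
    if (!is.null(spec$crossGroupEdges)) {
        e <- spec$crossGroupEdges
        for (k in seq_len(nrow(e)))
            R[e$i[k], e$j[k]] <- R[e$j[k], e$i[k]] <- e$r[k]
    }
    # Repair indefiniteness from planted edges by eigenvalue clipping,
    # then renormalize to unit diagonal.
    eg <- eigen(R, symmetric = TRUE)
    if (min(eg$values) < 1e-8) {
        ev <- pmax(eg$values, 1e-6)
        R <- eg$vectors %*% (ev * t(eg$vectors))
        s <- sqrt(diag(R))
        R <- R / tcrossprod(s)
    }
    list(R = R, factorOf = factorOf, groupOf = groupOf, load = load,
         noise = noise)
}

#' Simulate a behavioral MeasureMatrix with known covariance
#'
#' Draws individuals from a multivariate normal with the block-factor
#' correlation implied by the spec, applies per-batch mean/variance
#' shifts, and masks entries missing. The ground-truth correlation matrix
#' and generating structure are attached as
#' `metadata(result)$truth`.
#'
#' @param spec a [measureTruthSpec()].
#' @return A \linkS4class{MeasureMatrix}. Identical specs (including seed)
#'   give bit-identical output.
#' @examples
#' spec <- measureTruthSpec(nIndividuals = 100,
#'     groups = data.frame(group = c("act", "photo"), nMeasures = 5,
#'                         nFactors = 1, loading = 0.8), seed = 42)
#' m <- simulateMeasureMatrix(spec)
#' dim(m)
#' @export
simulateMeasureMatrix <- function(spec) {
    stopifnot(inherits(spec, "MeasureTruthSpec"))
    truth <- truthCorrelation(spec)
    d <- ncol(truth$R)
    n <- spec$nIndividuals
    set.seed(spec$seed)
    L <- chol(truth$R + diag(1e-10, d))
    X <- matrix(rnorm(n * d), n, d) %*% L

    batchOf <- rep(spec$batches$batch, spec$batches$size)
    for (k in seq_len(nrow(spec$batches))) {
        rows <- which(batchOf == spec$batches$batch[k])
        X[rows, ] <- X[rows, ] * sqrt(spec$batches$varScale[k]) +
            spec$batches$meanShift[k]
    }

    if (spec$missingRate > 0) {
        if (spec$missingMechanism == "mcar") {
            mask <- matrix(runif(n * d) < spec$missingRate, n, d)
        } else {
            # Activity-linked: rows with low first-measure values lose
            # entries more often (logistic link centered on the mean rate).
            act <- scale(X[, 1L])[, 1L]
            pRow <- stats::plogis(stats::qlogis(
                pmin(pmax(spec$missingRate, 1e-3), 1 - 1e-3)) - act)
            mask <- matrix(runif(n * d) < pRow[row(matrix(0, n, d))], n, d)
        }
        # Never empty a full row or column.
        for (i in which(rowSums(!mask) == 0L)) mask[i, sample.int(d, 1L)] <- FALSE
        for (j in which(colSums(!mask) == 0L)) mask[sample.int(n, 1L), j] <- FALSE
        X[mask] <- NA_real_
    }

    m <- MeasureMatrix(X, batch = batchOf, assay = truth$groupOf,
                       measure = sprintf("m%02d", seq_len(d)),
                       group = truth$groupOf)
    metadata(m)$truth <- list(correlation = truth$R,
                              factorOf = truth$factorOf,
                              loading = truth$load, noiseSd = truth$noise,
                              spec = spec)
    m
}

#' Simulate Markov turn sequences
#'
#' Directions follow a two-state Markov chain with flip probability
#' `switchProb` (the first direction is a fair coin). Inter-turn intervals
#' are exponential with unit rate (`"poisson"`) or drawn from a two-rate
#' bursty process that alternates between a high and a low event rate with
#' geometric dwell times (`"bursty"`).
#'
#' @param nIndividuals number of sequences.
#' @param nTurns turns per sequence (>= 2).
#' @param switchProb probability that a turn's direction differs from the
#'   previous turn's.
#' @param timing `"poisson"` or `"bursty"`.
#' @param rateHi,rateLo event rates of the bursty states.
#' @param dwell expected number of events spent in each bursty state.
#' @param seed integer seed.
#' @return List of \linkS4class{TurnSequence} objects.
#' @export
simulateTurnSequences <- function(nIndividuals, nTurns, switchProb = 0.5,
                                  timing = c("poisson", "bursty"),
                                  rateHi = 10, rateLo = 1, dwell = 20,
                                  seed = 1L) {
    timing <- match.arg(timing)
    if (nTurns < 2L) stop("nTurns must be at least 2")
    if (switchProb < 0 || switchProb > 1)
        stop("switchProb must lie in [0, 1]")
    set.seed(as.integer(seed))
    lapply(seq_len(nIndividuals), function(i) {
        flips <- runif(nTurns - 1L) < switchProb
        dirIdx <- cumsum(c(sample(0:1, 1L), flips)) %% 2L
        dirs <- c("L", "R")[dirIdx + 1L]
        if (timing == "poisson") {
            iti <- rexp(nTurns)
        } else {
            state <- logical(nTurns)   # TRUE = high-rate state
            s <- TRUE
            t <- 1L
            while (t <= nTurns) {
                len <- min(1L + rgeom(1L, 1 / dwell), nTurns - t + 1L)
                state[t:(t + len - 1L)] <- s
                s <- !s
                t <- t + len
            }
            iti <- rexp(nTurns, rate = ifelse(state, rateHi, rateLo))
        }
        TurnSequence(cumsum(iti), dirs)
    })
}

#' Specify the ground truth of a synthetic expression dataset
#'
#' @param nGenes number of genes.
#' @param librarySizeMean mean per-individual library size (reads).
#' @param fracCoupled fraction of genes linearly coupled to a behavior.
#' @param effectSize slope of log-expression on the (z-scored) coupled
#'   behavior.
#' @param pathwaySizes gene-set sizes for [simulatePathways()].
#' @param bioNoiseSd SD of per-individual biological log-expression noise.
#' @param seed integer seed.
#' @return A classed list (`ExpressionTruthSpec`).
#' @export
expressionTruthSpec <- function(nGenes, librarySizeMean = 2e6,
                                fracCoupled = 0.05, effectSize = 0.5,
                                pathwaySizes = c(30, 30, 30),
                                bioNoiseSd = 0.2, seed = 1L) {
    if (fracCoupled < 0 || fracCoupled > 1)
        stop("fracCoupled must lie in [0, 1]")
    if (any(pathwaySizes > nGenes))
        stop("pathway sizes cannot exceed the gene universe")
    structure(list(nGenes = as.integer(nGenes),
                   librarySizeMean = librarySizeMean,
                   fracCoupled = fracCoupled, effectSize = effectSize,
                   pathwaySizes = as.integer(pathwaySizes),
                   bioNoiseSd = bioNoiseSd, seed = as.integer(seed)),
              class = "ExpressionTruthSpec")
}

#' Simulate a gene-by-individual count matrix coupled to behaviors
#'
#' Each coupled gene's log relative abundance depends linearly (slope
#' `effectSize`) on one designated behavioral measure; uncoupled genes
#' vary independently. Counts are Poisson draws against per-individual
#' library sizes (uniform on 0.5-1.5x the mean). The coupled-gene
#' registry and library sizes are stored in `metadata()` of the result.
#'
#' @param spec an [expressionTruthSpec()].
#' @param behaviors a \linkS4class{MeasureMatrix} with at least one
#'   measure; coupled behaviors are assigned round-robin over its columns
#'   and missing behavior values are treated as 0 (the measure mean on the
#'   z-scale) when generating.
#' @return An \linkS4class{ExpressionDataset} with a `"counts"` assay;
#'   `metadata(.)$registry` is a data.frame of (gene, behavior,
#'   effectSize) truths.
#' @export
simulateExpression <- function(spec, behaviors) {
    stopifnot(inherits(spec, "ExpressionTruthSpec"),
              is(behaviors, "MeasureMatrix"))
    if (nMeasures(behaviors) < 1L)
        stop("behaviors must carry at least one measure")
    nG <- spec$nGenes
    B <- measureValues(behaviors)
    B[is.na(B)] <- 0
    n <- nrow(B)
    nCoupled <- round(spec$fracCoupled * nG)
    if (nCoupled < 1L && spec$effectSize != 0)
        warning("fracCoupled * nGenes < 1: no couplings will be planted")
    set.seed(spec$seed)
    baseLog <- rnorm(nG, mean = log(100), sd = 1)   # relative abundance
    coupledGenes <- if (nCoupled >= 1L) sample.int(nG, nCoupled)
                    else integer()
    coupledBehav <- rep_len(seq_len(ncol(B)), length(coupledGenes))
    # Alternate effect signs so planted effects cancel compositionally:
    # same-signed effects would shift whole library compositions with the
    # behavior and leak the signal into every gene's RPM.
    effects <- spec$effectSize *
        rep_len(c(1, -1), length(coupledGenes))

    logExpr <- matrix(baseLog, nG, n) +
        matrix(rnorm(nG * n, sd = spec$bioNoiseSd), nG, n)
    for (k in seq_along(coupledGenes))
        logExpr[coupledGenes[k], ] <- logExpr[coupledGenes[k], ] +
            effects[k] * B[, coupledBehav[k]]

    rel <- exp(logExpr)
    rel <- sweep(rel, 2L, colSums(rel), "/")
    lib <- round(spec$librarySizeMean * runif(n, 0.5, 1.5))
    lambda <- sweep(rel, 2L, lib, "*")
    counts <- matrix(rpois(nG * n, lambda), nG, n,
                     dimnames = list(sprintf("gene_%05d", seq_len(nG)),
                                     rownames(B)))
    ed <- ExpressionDataset(counts)
    registry <- if (length(coupledGenes) && spec$effectSize != 0) {
        data.frame(gene = rownames(counts)[coupledGenes],
                   behavior = colnames(B)[coupledBehav],
                   effectSize = effects)
    } else {
        data.frame(gene = character(), behavior = character(),
                   effectSize = numeric())
    }
    metadata(ed)$registry <- registry
    metadata(ed)$librarySizes <- lib
    ed
}

#' Simulate a gene-set (pathway) annotation
#'
#' Draws gene sets of the sizes in the spec from the gene universe; the
#' first ("designated") pathway is over-populated with coupled genes so
#' that a fraction `enrichedFraction` of its members are coupled.
#'
#' @param spec an [expressionTruthSpec()].
#' @param coupledGenes character vector of coupled gene ids (e.g., the
#'   registry of [simulateExpression()]).
#' @param enrichedFraction fraction of the designated pathway drawn from
#'   `coupledGenes` (0 = uniform like the rest).
#' @param geneUniverse optional character vector of all gene ids; default
#'   `gene_00001..gene_<nGenes>`.
#' @param seed integer seed (defaults to the spec's).
#' @return Named list of character vectors (one per pathway), suitable for
#'   [writeGmt()].
#' @export
simulatePathways <- function(spec, coupledGenes, enrichedFraction = 0.8,
                             geneUniverse = NULL, seed = NULL) {
    stopifnot(inherits(spec, "ExpressionTruthSpec"))
    if (is.null(geneUniverse))
        geneUniverse <- sprintf("gene_%05d", seq_len(spec$nGenes))
    if (is.null(seed)) seed <- spec$seed
    set.seed(as.integer(seed))
    sets <- vector("list", length(spec$pathwaySizes))
    names(sets) <- sprintf("pathway_%02d", seq_along(sets))
    for (k in seq_along(sets)) {
        sz <- spec$pathwaySizes[k]
        if (k == 1L && enrichedFraction > 0 && length(coupledGenes)) {
            nC <- min(round(enrichedFraction * sz), length(coupledGenes))
            rest <- sample(setdiff(geneUniverse, coupledGenes), sz - nC)
            sets[[k]] <- sample(c(sample(coupledGenes, nC), rest))
        } else {
            sets[[k]] <- sample(geneUniverse, sz)
        }
    }
    sets
}
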