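---
title: "Dissecting the covariance structure of individual behavioral variation"
author: "behavarium maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the covariance structure of individual behavioral variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavarium)
```

## The problem

When many individuals of a single genotype, reared in a common
environment, are pushed through a battery of behavioral assays over days,
they still differ — persistently — in activity, phototaxis, locomotor
handedness, turn timing, and dozens of other measures. The scientific
question this package addresses is about the *joint* structure of those
differences: do individual biases collapse onto a few latent personality
axes, or do they span many nearly independent dimensions with only sparse
couplings? Answering it requires a pipeline that (i) assembles a single
individuals × measures matrix from heterogeneous batches, (ii) completes
its missing entries without distorting the correlation structure, (iii)
removes the correlations one would expect trivially, and (iv) quantifies
what significant structure remains and at what dimensionality.

`behavarium` implements that pipeline end to end, together with a
synthetic-data generator that plants known covariance, missingness, batch
effects, turn-sequence statistics and gene–behavior couplings, so every
stage can be validated against ground truth without any external data.

## Matrix assembly

Raw measures differ in scale and carry batch effects on both mean and
dispersion. `zscoreByBatch()` standardizes every measure within every
batch to mean 0 and sample (n−1) SD 1 over its non-missing entries.
The sample SD is a convention choice; nothing downstream depends on the
n vs n−1 distinction beyond a constant factor. A zero-variance
batch×measure block is mapped to 0 — its batch mean — rather than to
missing, so later PCA sees a defined value; the event is warned about.

`matchAndConcatenate()` merges two experiments by `(assay, measure)`
key. Because assay order is typically randomized between experiments,
day of testing is ignored for matching — except for circadian-class
assays, whose measures recur daily and are matched by day. Cells without
a partner become missing, and the merged matrix is re-z-scored by
measure. We do **not** re-standardize again after imputation: the
completed values inherit the observed scale, and re-scaling after
infilling would break the observed-entry fidelity contract.

## Missing-data completion

Missing entries (typically ~23% in this kind of serial phenotyping) are
completed by alternating least squares: a rank-r factor model
\(X \approx U V^{\top}\) fit to the observed entries only, with seeded
standard-normal initialization of \(U\), ridge-stabilized per-row and
per-column solves, and convergence declared when the relative change of
the observed-entry residual norm drops below `tol` (default `1e-6`,
`maxIter = 200`). Observed entries are restored exactly in the output;
only missing cells take the low-rank estimate — single ALS runs could
otherwise drift observed values toward the fit.

A single ALS completion depends on its initialization, so
`medianAlsImpute()` aggregates 200 repetitions (the default; each with a
seed derived deterministically from the base seed) by the cell-wise
median. The median aggregate is chosen for *correlation-structure*
recovery rather than squared error: `evaluateImputation()` shows, on
factor-structured synthetic matrices, that median ALS beats column-mean
infilling on the Frobenius distance between completed and true
correlation matrices even where its per-cell RMSE is not the best, and
that on structure-free noise mean infilling is not worse in RMSE. That
asymmetry is exactly why this pipeline selects its imputer by
correlation distance.

The factor rank is not something the data's provenance dictates, so the
default (`rank = "auto"`) selects it by held-out reconstruction error: 5%
of observed cells are hidden (never emptying a row or column), candidate
ranks 1–10 are fit, and the rank minimizing held-out RMSE wins. The rank
can always be set explicitly.

## Distillation: removing expected correlations

Many strong correlations are expected *a priori* — near-duplicate
measures, or measures reflecting one underlying propensity such as
general activity. Users declare such groups (via `groupLabels()` or a
YAML selector config, `applyGroupConfig()`), and `distill()` replaces
each group's submatrix with its projection onto the group's
*shuffle-significant* principal components.

The retention rule is parallel-analysis-style: each rank's variance
explained is compared against the same matrix with every column
independently permuted across individuals (`nShuffles = 250` by default;
the confidence level, 95%, is part of the procedure, the shuffle count is
ours). A rank counts as significant when its variance explained is **at
or above the lower bound** of the null confidence interval at that rank
— "above or within" the null band — and the retained set is the maximal
*prefix* of such ranks, with a minimum of one. The prefix rule resolves
what to do with a non-contiguous pattern (rank 3 passing while rank 2
fails): we keep the contiguous head only, since retaining a PC whose
senior sibling failed has no clean variance-ordering interpretation.
Ties at the boundary count as within, hence retained.

Two consequences deserve flagging. First, the rule is deliberately
permissive: on a pure-noise group the observed spectrum is itself a draw
from the shuffle null, so most ranks sit above the lower CI bound and
the retained count approaches the group size. Our tests assert this
behavior as a documented property of the rule, not a virtue. Second, PC
signs are arbitrary; we fix them by making each PC's largest-magnitude
loading positive, so repeated runs are bit-identical.

PCA is run on the correlation scale (columns z-scored), consistent with
the upstream normalization, and distilled columns are re-z-scored.

## Correlation significance and the bootstrap FDR

All correlations are Spearman rank correlations (average ranks on ties),
with two-tailed p-values from the t-transform
\(t = r\sqrt{(n-2)/(1-r^2)}\). Pairs with \(|r| = 1\) are reported as
p = 0 and flagged ( the transform is undefined there); constant columns
yield undefined correlations, reported missing. At n = 6 the t-transform
agrees with the exact 720-ordering permutation p to within 0.05, which
is the regime the tests pin down.

The false discovery rate attached to a significance threshold α is
estimated by a density ratio. The matrix is bootstrap resampled over
individuals (100 repetitions by default); p-values of all unique measure
pairs are pooled into a mean kernel density estimate. The same procedure
on independence-null matrices (each column independently shuffled, then
resampled) gives a null density, and

\[ \widehat{\mathrm{FDR}}(\alpha) \;=\; \frac{\bar f_{\text{null}}(\alpha)}{\bar f_{\text{obs}}(\alpha)}. \]

The KDE uses a Gaussian kernel, Silverman bandwidth, and boundary
reflection on \([0, 1]\) (p-value densities have mass piled at 0; an
unreflected kernel would halve it). The ratio is evaluated *pointwise*
at α, matching the working definition above; a tail-mass variant
(densities integrated over \([0, \alpha]\)) is available via
`tailRatio = TRUE`. Where the observed density is numerically zero the
estimate is capped (default 10) with a warning.

Two calibration facts matter for interpretation. Under a global null the
ratio is ≈ 1 for all α — our tests hold its mean at α = 0.05 inside
[0.7, 1.3] over 50 simulations. With strongly separated planted signal,
however, the pointwise ratio behaves as a *local* fdr at the threshold:
it stays conservative (well above the realized false-discovery
proportion, which concentrates near 0 when signal p-values are ≪ α)
while still dropping far below its null value of 1. It should be read as
"density of nulls relative to everything at p = α", not as the tail FDP
of the significant set.

`corrOfCorrsBootstrap()` compares two datasets' correlation structures:
individuals are resampled within each matrix, unique off-diagonal
r-values are vectorized, and the Spearman correlation between the two
vectors is recorded over 100 repetitions.

## The connected-components spectrum

A single number cannot summarize how organized a correlation matrix is,
so the spectrum sweeps 200 thresholds uniformly between the minimum and
maximum off-diagonal \(|r|\) and, at each, counts connected components
of the graph with an edge wherever \(|r| >\) threshold (strict, so the
k = d endpoint is always reached at the top threshold). The histogram of
counts over the sweep profiles organization across dimensionalities:
mass at k = 1 means one network of at least weak couplings, mass at
k = d means fully uncorrelated measures, intermediate mass means
intermediate-scale structure. Absolute correlation is thresholded —
on z-scored data correlation and covariance coincide up to sign, and
thresholding \(|r|\) treats anti-correlated coupling as coupling.

The sweep is computed incrementally: edges sorted once by weight, a
union-find grown as thresholds descend, so the full 200-threshold
spectrum costs one sort plus one pass. Equivalence with an independent
transitive-closure component counter is asserted exactly on 1000 random
matrices up to d = 8. When all off-diagonal values are equal the sweep
is degenerate; the spectrum is flagged and all mass sits at the single
resulting count. Both the normalized histogram and raw threshold counts
are stored. `dropMeasureRobustness()` repeats the spectrum after
removing random measure subsets to show which features depend on
specific measures.

## Turn statistics

Three higher-order statistics summarize timed binary-choice streams:

* **handedness** — the fraction of right turns;
* **switchiness** — the plug-in mutual information (bits, base 2)
  between consecutive turn directions, estimated from the n−1 adjacent
  pairs with \(0\log 0 \equiv 0\). Deterministic alternation gives 1
  bit, independence 0; for a stationary flip-probability-q chain the
  closed form is \(1 - H_2(q)\), which the estimator matches to < 0.005
  bits at n = 10^5. No small-sample bias correction is applied by
  default; Miller–Madow is available via `correction`. Note the MI is
  symmetric in persistence: both strong alternation and strong
  perseveration score high;
* **clumpiness** — the coefficient of variation of inter-turn intervals:
  0 for periodic, 1 for Poisson, > 1 for bursty timing. Scale-free, so
  uniform time rescaling leaves it unchanged.

These are our operationalizations of "variation in inter-turn interval"
and "mutual information in the direction of subsequent turns"; an
alternative switchiness reading — switches normalized by the expectation
under the individual's own bias — is not implemented, and would differ
for strongly biased individuals. `transitionMatrix()` row-normalizes
adjacent-state counts for discrete behavioral-state sequences (rows
never left are all-missing and flagged), and `perConditionStats()`
computes each statistic independently within condition labels such as
permissive/restrictive temperature blocks.

## The expression screen

`filterAndNormalize()` applies the standard pre-processing ladder: drop
individuals under 1M total reads (the stricter of the two conventional
cutoffs; configurable), convert to reads per million, drop genes under
10 mean RPM across retained individuals, and quantile-normalize
(average-rank ties, via limma) so every individual shares one expression
distribution.

`fitGeneBehaviorModels()` fits one OLS model per (gene, behavior) pair —
behavior on single-gene normalized expression — and reports slope, r²
and the two-tailed slope p. Deliberately, **no multiple-testing
correction** is applied at this stage; per-behavior gene lists are
thresholded at raw p < 0.05 and the correction burden moves to the
enrichment step. `enrich()` scores each user-supplied gene set (GMT) by
the hypergeometric upper tail of its overlap with the list, against the
*post-filter* gene universe (not the full annotation — the background
must be the genes that could have been called), with Benjamini–Hochberg
adjustment across sets within each behavior. Cross-behavior summaries
are unions of per-behavior significant sets. `bootstrapEnrichment()`
reruns screen + enrichment on resamples of individuals (500 replicates
by default, drawn downstream of quantile normalization), reporting per
(set, behavior) the probability of significance and per set the mean of
the maximum −log10 adjusted p over behaviors; `shuffle = TRUE` permutes
behavior rows first, giving the null control.

## What the generator emulates — and what it does not

`simulateMeasureMatrix()` draws individuals from a multivariate normal
whose correlation comes from a block-factor model: each group carries
its own latent factors, measures load on one factor each (round-robin),
unique noise brings each measure to unit variance, and optional
cross-group edges plant target correlations (with eigenvalue clipping
and re-normalization if the planted matrix leaves the PSD cone). Batch
effects are an additive mean shift plus a multiplicative variance scale
— exactly the family that per-batch z-scoring can remove, which is the
point: the generator tests the pipeline's assumptions, not their
violation. Missingness is missing-completely-at-random at a default
rate of 0.23, a typical missingness level for serial multi-assay
phenotyping. Real missingness is plausibly activity-linked (animals
failing assay-specific activity cutoffs), i.e. not MCAR; an
`missingMechanism = "activity"` mode ties a row's missingness to its
first measure for robustness studies, but MCAR is the tested default
because it makes the imputation contracts checkable. Passing tests
therefore certify behavior under MCAR and Gaussian factor structure —
not under informative missingness, heavy tails, or nonlinear couplings.

`simulateTurnSequences()` draws directions from a two-state Markov chain
with flip probability `switchProb` and intervals from either a unit-rate
Poisson process or a two-rate bursty alternation with geometric dwell.
`simulateExpression()` plants gene–behavior couplings on the log scale
with **alternating signs**: same-signed effects would shift whole
library compositions together with the behavior and leak the planted
signal into every gene's RPM — a compositional artifact, not a power
feature. Counts are Poisson against per-individual library sizes
(uniform 0.5–1.5× the mean); no overdispersion is modeled, because the
screen operates on normalized expression with Gaussian-ish biological
noise (`bioNoiseSd`, default 0.2) dominating the counting noise at the
default depths. `simulatePathways()` over-populates one designated gene
set with coupled genes at a chosen fraction.

## Problem sizes and numerical choices

The shipped validation suite runs at deliberately compact sizes chosen
to exercise each estimator in its asymptotic regime while keeping the
whole suite in minutes: imputation benchmarks at n = 500 × d = 40 with
2 factors, 25% masked, 50 ALS repetitions, 20 replicates; PC-count
recovery at n = 500, 10 measures, 250 shuffles, 50 replicates per factor
count; FDR calibration at n = 200 × d = 20 with 25 bootstrap repetitions
and 50 replicates; turn-statistic closed forms at n = 10^5 events;
screen calibration at 500 genes × 10 behaviors × 100 individuals; exact
enrichment enumeration on backgrounds up to 12 genes. The acceptance
script (`scripts/acceptance.R`) recomputes the same families of
quantities at these sizes from a single seed.

Other numerical choices: ALS ridge `1e-8` on the normal equations;
missing entries implicitly start at 0 (the measure mean after
z-scoring) via the zero initialization of \(V\); repetition seeds drawn
by `sample.int` from the base seed; KDE grid of 512 points on [0, 1];
eigen-decomposition of correlation matrices uses `eigen(symmetric =
TRUE)` with negative eigenvalues clipped at 0 when normalizing variance
fractions.

## Limitations

* The FDR density ratio is a local quantity (see above); tail FDP
  requires `tailRatio = TRUE` and is still KDE-smoothed.
* The PC-retention rule's permissiveness on unstructured groups inflates
  distilled width for noise-dominated groups.
* ALS assumes an approximately low-rank signal; under MNAR missingness
  its completions are biased, and the generator's activity-linked mode
  exists precisely to explore that failure.
* The expression screen is marginal per gene: correlated genes yield
  correlated models, and the enrichment bootstrap — not the screen —
  is the reproducibility control.
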