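Package: behavarium
Title: Covariance Structure of Individual Behavioral Variation
Version: 0.3.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing the covariance structure of individual
    behavioral variation in high-throughput phenotyping experiments.
    Assembles individual-by-measure behavioral matrices across batches
    with batch- and measure-wise standardization, completes missing
    entries by median-aggregated alternating least squares, collapses
    a-priori measure groups onto their shuffle-significant principal
    components, estimates sparse-correlation significance with a
    bootstrap kernel-density false discovery rate, profiles correlation
    matrix dimensionality with a connected-components spectrum, derives
    higher-order turn statistics (handedness, switchiness, clumpiness,
    state transition matrices) from event streams, and screens gene
    expression against behavior with single-gene linear models and
    hypergeometric gene-set enrichment. A synthetic-data generator with
    known ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    limma,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, StatisticalMethod, GeneExpression, Regression
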