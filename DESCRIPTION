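Package: breakgene
Title: Recurrent Chromosomal Breakpoint Genes from Segmented Copy-Number
    Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects copy-number-aberration-associated chromosomal
    breakpoints in segmented, state-called array-CGH profiles, maps them
    to genes, and tests per-gene breakpoint recurrence against a
    gene- and profile-specific Poisson-binomial null with a discrete
    Benjamini-Hochberg-type false discovery rate correction. Downstream,
    samples are stratified by network-based stratification (network
    propagation of merged breakpoint and mutation events followed by
    graph-regularized non-negative matrix factorization with consensus
    clustering), per-sample network-based gene aberration scores are
    extracted from the factorization, and subtypes are linked to outcome
    by Kaplan-Meier, log-rank, Cox and Fisher exact analyses. A synthetic
    cohort generator with known ground truth supports calibration and
    power studies of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    Matrix,
    igraph,
    IRanges,
    limma,
    survival
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
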