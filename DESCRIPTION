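Package: psapgp
Title: Population-Structure-Aware Across-Population Genomic Prediction for Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic selection toolkit for across-population prediction of
    hybrid performance. Implements additive genomic relationship (VanRaden)
    kinship with 2x2 training/breeding block partitioning, MeanRel-based
    training-set optimization, population-structure covariates (principal
    components, partitioning-around-medoids one-hot memberships, and an
    admixture Q-matrix estimated by an EM maximum-likelihood algorithm) used
    as fixed effects inside GBLUP (exact REML via eigendecomposition) and
    BayesB (single-site Gibbs sampler with a point-mass/scaled-t mixture
    prior), within-population repeated k-fold cross-validation,
    across-population prediction runs, and a synthetic-data generator
    emulating admixed inbred parents crossed into F1 hybrid populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    cluster,
    jsonlite,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
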