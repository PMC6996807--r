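Package: rrgp
Title: Random Regression Models for Genomic Prediction of Longitudinal Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single- and multi-trait random regression models (RRM) on Legendre
    polynomial bases for genomic analysis of time-valued traits, in the style of
    longitudinal "animal model" analyses applied to high-throughput plant
    phenotyping. Provides genomic relationship matrix construction from SNP
    dosages with quality-control filters, assembly of the RRM mixed model with
    additive-genetic and permanent-environment covariance functions and
    day-specific (heterogeneous) residual (co)variances, Bayesian estimation of
    the coefficient (co)variance matrices by Gibbs sampling, BLUP/BLUE solving
    of Henderson's mixed model equations at fixed variances, per-day narrow-sense
    heritability and genomic-correlation trajectories, cross-validation scenarios
    for predicting unphenotyped accessions and for forecasting future time
    points, and a synthetic-data generator emulating a bivariate greenhouse
    experiment (daily water use and projected shoot area).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    lme4,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma
Config/testthat/edition: 3
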