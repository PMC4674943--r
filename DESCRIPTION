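Package: vargwas
Title: Genetic Analysis of Trait Means and Residual Variance with DHGLM and Bayesian GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for the quantitative-genetic analysis of a repeatedly
    recorded trait (litter size in pigs being the motivating case) and of the
    heterogeneity of its residual variance. Provides pedigree utilities
    (inbreeding, numerator relationship matrices), a sparse average-information
    REML engine for weighted univariate and bivariate animal models, an
    iterative double hierarchical generalized linear model (DHGLM) that couples
    a Gaussian mean model with a log-linear model for the residual variance,
    deregression of estimated breeding values with reliabilities and weights,
    genotype quality control, and a multi-SNP Bayesian variable-selection
    genome-wide association analysis reporting Bayes factors, allele
    substitution effects and variance explained. Includes a synthetic-data
    generator with planted mean QTL and variance QTL (vQTL) so the whole
    pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    coda,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
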