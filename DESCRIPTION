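Package: tampath
Title: Bayesian Pathway Analysis of Early Tamoxifen Discontinuation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for pharmacogenetic analysis of early
    tamoxifen discontinuation in breast cancer cohorts. Generates synthetic
    pharmacogenetic cohorts with supply-diary dispensing records, derives the
    182-consecutive-day gap discontinuation endpoint, performs genotype quality
    control (minor allele frequency, Hardy-Weinberg equilibrium) and chained
    multiple imputation of missing genotypes, screens variants with adjusted
    Cox proportional-hazards models with empirical-Bayes shrinkage, and runs a
    Metropolis-Hastings search over pathway-constrained multiplicative
    gene-interaction trees scored by Laplace-approximated Cox marginal
    likelihoods, reporting Bayes Factors for variants, pathway concepts and
    trees, together with genotype-combination hazard-ratio grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    survival,
    stats,
    utils,
    yaml,
    jsonlite,
    MASS,
    nnet
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
RoxygenNote: 7.3.3
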