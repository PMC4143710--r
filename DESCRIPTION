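Package: pedT2
Title: Extended T2 Association Tests for Longitudinal Family Sequencing Data
Version: 0.1.0
Authors@R:
    person("J.", "Carrow", email = "jcarrow@example.org", role = c("aut", "cre"))
Description: Family-based case/control association testing for whole-genome
    sequencing data using generalized and extended Hotelling T2 statistics.
    The tests jointly model three correlation sources: linkage disequilibrium
    among variants, kinship among pedigree members, and serial correlation of
    longitudinally repeated covariates, via a Kronecker-structured covariance.
    Rare variants (MAF < 0.05) are collapsed between adjacent common variants
    (sum or max CMC schemes) within fixed-width genome windows. Inference is
    asymptotic (chi-square, variable-count or rank degrees of freedom) or by a
    genotype-only permutation null. Includes a gene-dropping pedigree
    simulator with haplotype-pool linkage disequilibrium, longitudinal
    covariate and event models, genomic-inflation and power/type-I-error
    evaluation utilities, and a command-line scan driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    Rcpp,
    VariantAnnotation
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
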