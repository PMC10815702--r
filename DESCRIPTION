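Package: iecatrc
Title: Case-Control Association Tests with Regression-Calibrated External Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-variant case-control association testing that integrates
    external control samples after regression-calibrating their genotypes
    against the internal-control genotype distribution, so that batch effects
    between studies (platform, calling pipeline, stratification) do not
    inflate type I error. Provides the covariate-adjusted logistic score
    test, saddlepoint-approximation p-values for unbalanced case-control
    ratios, efficient-resampling p-values for low minor-allele counts, naive
    and internal-only comparison strategies, a full simulation engine for
    type-I-error and power experiments under batch-effect mechanisms, and
    VCF/delimited-matrix input-output with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    optparse,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
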