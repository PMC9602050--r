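Package: shaher
Title: Shared Heritability Decomposition for Sets of Genetically Correlated Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decomposes the heritability of a set of genetically correlated
    traits into components explained by shared and unshared genetic factors,
    working only from per-trait GWAS summary statistics plus genetic and
    phenotypic correlation matrices. Estimates per-trait shared-heritability
    proportions from the genetic correlation matrix, constructs the shared
    genetic impact trait (SGIT) as the linear combination of traits
    maximizing heritability explained by shared factors, derives per-trait
    unshared impact traits (UGITs) by genetic residualization, and produces
    GWAS summary statistics for all combined traits with sample-overlap-aware
    standard errors and effective sample sizes. Includes a simulation engine
    for validating the estimators, an individual-level cohort generator for
    end-to-end checks, and locus-level post-processing (distance clumping,
    novel-locus calls, locus overlap matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
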