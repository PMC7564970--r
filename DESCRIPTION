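Package: detraingps
Title: Data-Driven Genetic Predisposition Scores for Muscular Change
    After Training Cessation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the polygenic association between candidate
    muscle-related SNPs and changes in skeletal muscle mass and knee
    strength in older adults after a structured training programme stops.
    Implements genotype panel quality control (call-rate and monomorphic
    filters, linkage-disequilibrium subgrouping with representative
    selection), phenotype derivation from bioelectrical impedance via the
    Janssen skeletal muscle mass equation, phenotype-driven SNP selection
    by classical stepwise regression, favourable-allele genetic
    predisposition score (GPS) construction, general-linear-model
    evaluation with Type-III partial r-squared, covariate-adjusted GPS bin
    summaries, and honest assessment of selection bias through
    cross-validation, permutation nulls and parameter-recovery
    simulations on a built-in synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
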