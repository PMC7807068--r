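Package: riskforest
Title: Random Survival Forest and GMDR Risk Profiling for Gene-Lifestyle
    Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-GWAS risk profiling for right-censored cohort studies that
    combine genotype panels with lifestyle covariates. Provides a from-scratch
    random survival forest (bootstrap trees with log-rank splitting, ensemble
    Nelson-Aalen cumulative hazards, out-of-bag concordance, minimal depth and
    permutation variable importance), a two-stage multimodal variable
    selection built on nested-model error curves and drop-error rates,
    generalized multifactor dimensionality reduction (GMDR) for gene-gene
    interaction model search with cross-validation consistency and permutation
    testing, and combined genotype-lifestyle dose-response profiling via Cox
    proportional hazards models with Benjamini-Hochberg correction and
    Schoenfeld diagnostics. Includes a calibrated synthetic-cohort generator
    (Hardy-Weinberg genotypes, realistic lifestyle distributions, plantable
    proportional-hazards effects) so the full pipeline is testable without
    access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
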