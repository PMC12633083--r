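Package: polyhte
Title: Polygenic Heterogeneous Treatment Effect Inference for Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Causal transfer-learning tools for detecting and characterizing
    genetically driven heterogeneous treatment effects (HTE) in randomized
    controlled trials. Treatment response is modelled as a function of many
    pre-trained polygenic risk scores (PRS) under a polygenic
    gene-by-treatment interaction model. Provides an individual-level
    pipeline (pseudo-outcome sequential cross-fitting, best-linear-projection
    heterogeneity test, quantile subgroup average treatment effects, PRS
    importance ranking), a summary-statistic pipeline (per-PRS
    treatment-interaction z tests from genome-wide interaction study and GWAS
    summary statistics, aggregated with the Cauchy combination test), analytic
    power scaling laws for the PES-by-treatment interaction test, comparison
    baselines (single-PRS interaction, within-sample GWIS, two-score
    pharmacogenomic regression, SNP-feature learner), and a synthetic-data
    engine with a correlated polygenic-score panel and unit-variance outcome
    model for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    MASS,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
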