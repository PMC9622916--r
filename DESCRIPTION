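Package: bpgrs
Title: Blood Pressure by Genetic Risk Score Interaction Analysis for
    Urothelial Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a gene-environment interaction analysis pipeline for
    incident urothelial carcinoma in men: a weighted bladder-cancer genetic
    risk score built from 18 GWAS variants, cause-specific Cox proportional
    hazards models on the attained-age time scale, additive interaction
    quantified by the relative excess risk due to interaction (RERI) with
    delta-method confidence intervals, multiplicative interaction via the
    likelihood-ratio test, and 20-year absolute risk with death as a
    competing event. A synthetic cohort generator with a known, injectable
    gene-environment interaction makes every stage testable without access
    to the original cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
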