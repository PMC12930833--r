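Package: metabocp
Title: Uncertainty-Aware CSF Metabolomics Diagnostics with Conformal Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for cerebrospinal-fluid (CSF) metabolomics
    diagnostics of idiopathic normal pressure hydrocephalus (iNPH):
    seeded synthetic cohort and LC-MS injection-sequence simulation,
    pooled-QC LOESS signal-drift correction and weekly median
    normalization, missingness filtering and half-minimum imputation,
    age- and sex-adjusted per-metabolite regression with ANOVA F-tests
    and Benjamini-Hochberg false discovery rate control, a discriminatory
    metabolite screen, PLS-DA classification with repeated stratified
    cross-validation, and a transductive (Mondrian) conformal prediction
    layer producing per-case p-values, prediction sets, calibration and
    label-distribution diagnostics, and confusion summaries.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    mixOmics,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
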