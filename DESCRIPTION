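Package: depimpute
Title: Dependence-Aware Weighted KNN Imputation for Paired Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes entirely missing paired samples (for example, normal-tissue
    miRNA profiles missing for a subset of subjects in a tumor-normal study) as
    convex combinations of the k nearest fully observed subjects, with
    neighbors found in a mixed-type demographic/lifestyle covariate space.
    Because imputed rows are linear combinations of observed rows, imputation
    induces statistical dependence between samples; the package constructs the
    induced covariance structure and provides a generalized-least-squares
    paired t-test that accounts for it, alongside dependence-ignoring and
    case-deletion analyses, Benjamini-Hochberg FDR adjustment, and a seeded
    simulation and evaluation framework (RMSE, TPR, FPR, FDR) for benchmarking
    imputation and testing strategies.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
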