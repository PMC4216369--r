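Package: mirsmoke
Title: Smoking-Status-Stratified miRNA Expression, Survival and Target
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for smoking-status-stratified analysis of
    miRNA sequencing (RPKM) data from paired tumor/normal cohorts:
    expression-detection filtering, Ward hierarchical clustering with
    cluster-composition tests, permutation-based differential expression
    between smoking groups, paired fold-change recurrence calling with
    Benjamini-Hochberg correction, smoking-status specificity and
    smoking-cessation reversibility classification, external-cohort
    validation, tertile-stratified Kaplan-Meier/log-rank and multivariate
    Cox survival analysis, and miRNA-target network construction. Includes
    a synthetic cohort generator with planted ground truth so every stage
    can be validated without access to patient data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
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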