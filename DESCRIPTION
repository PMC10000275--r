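Package: sncclock
Title: Circulating Small Noncoding RNA Aging Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for building aging clocks
    from circulating small noncoding RNA (sncRNA) expression profiles.
    Covers synthetic cohort simulation with known ground truth, sample
    quality control, TMM-scaled counts-per-million normalization,
    empirical-Bayes (ComBat-style) batch correction with principal-component
    diagnostics, from-scratch maximal and total information coefficient
    (MIC/TIC) screening for linear and nonlinear age association,
    age-group-stratified cross-validated age prediction with linear,
    penalized and tree-ensemble regressors, and rank-sum consensus
    identification of core age-related sncRNAs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    glmnet,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr
Config/testthat/edition: 3
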