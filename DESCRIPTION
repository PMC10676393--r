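Package: clpnet
Title: Cross-Lagged Panel Networks for Dichotomous Symptom Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimation of cross-lagged panel network (CLPN) models for
    multi-wave dichotomous symptom data via node-wise L1-penalized logistic
    regression with cross-validated penalty selection, with edge weights on
    the log-odds and odds-ratio scales and in-/out-expected-influence
    centrality. Includes cross-sectional Ising networks with extended-BIC
    model selection, nonparametric bootstrap edge accuracy, case-drop
    stability (CS-coefficient), edge and centrality difference tests,
    cross-network comparison statistics, item- and scale-level descriptives
    for dichotomous scales, a missing-data stage (Little's MCAR test,
    dropout models, chained-equations imputation with logistic models), and
    a seeded synthetic panel generator with covariates and monotone
    missing-at-random attrition for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    yaml,
    withr,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
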