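Package: clpnet
Title: Cross-Lagged Panel Network Analysis of Two-Wave Symptom Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates directed cross-lagged panel networks (CLPN) between
    Internet-use-purpose indicators and CES-D depressive-symptom items
    measured at two waves. Provides CES-D scoring with reverse-coded items,
    a latent-threshold synthetic panel generator with known cross-lagged
    ground truth, missingness diagnostics and multiple imputation by
    chained equations, per-outcome cross-validated elastic-net (LASSO)
    regression assembling a 15 x 15 directed coefficient matrix, expected
    influence and bridge expected influence centralities, and bootstrap
    stability analyses (case-dropping CS-coefficients, edge-weight
    confidence intervals, and difference tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    igraph,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    MASS,
    optparse,
    knitr
Config/testthat/edition: 3
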