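Package: ragtcausal
Title: Causal Responder Analysis for Robot-Assisted Gait Training Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies baseline factors that predict recovery of supervised
    walking after robot-assisted gait training in severe subacute stroke.
    Implements DirectLiNGAM causal discovery over coded clinical variables,
    bootstrap edge-stability selection with bidirectional-edge resolution and
    weakest-edge cycle repair, confirmatory logistic regression with Wald
    odds-ratio intervals, and L1-penalized logistic regression with
    cross-validated penalty selection. Ships a synthetic cohort simulator
    with a planted causal graph, a screening-cascade model, and
    descriptive-table utilities, so the full pipeline is testable without
    access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    jsonlite,
    rlang,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
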