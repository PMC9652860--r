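Package: edgeqnet
Title: Kinase-Substrate Edge Biomarkers for Phosphoproteomic Drug-Response
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts paired protein and phosphosite expression cohorts into
    kinase-substrate edge-strength features (state-stratified z-score
    products), screens differentially correlated kinase-substrate pairs,
    selects predictive edge biomarkers by a repeated-split elastic-net
    procedure, and fits per-drug penalized linear models predicting tumor
    cell growth inhibition (TCGI). Includes a synthetic-cohort generator
    with planted signal for ground-truth validation, JSON model
    persistence, and a command-line interface over the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
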