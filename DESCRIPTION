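Package: scenoset
Title: Objective Selection of Climate Change Scenarios for Ensemble
    Species Distribution Forecasting
Version: 0.1.0
Authors@R:
    person("Scenoset", "Developers", email = "scenoset@example.org",
           role = c("aut", "cre"))
Description: Reduces a large ensemble of climate-change scenarios (AOGCM x
    forcing combinations summarised by regional climate deltas) to a small
    representative subset using Ward-seeded k-means clustering, and provides
    the downstream machinery for ensemble species distribution forecasting:
    change-field projection of baseline climatologies, a split-sample
    occurrence-model protocol with AUC evaluation, AUC-weighted and
    double-weighted (AUC x cluster size) consensus maps, maxSSS thresholding,
    range gain/loss statistics, and a combinatorial sensitivity analysis of
    arbitrary climate-model selection. Ships a synthetic-fixture generator
    (virtual species on a smooth climate landscape) so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
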