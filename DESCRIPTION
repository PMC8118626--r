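Package: coactr
Title: Decoding Behavior from Correlated Activity in Neural Event Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting how a neural population encodes a binary
    behavioral variable from calcium-imaging data. Converts surround-corrected
    fluorescence traces into binary event rasters with a sigma-threshold
    cascade, builds behaviorally labeled rasters, generates surrogate rasters
    that destroy (swap shuffle) or preserve (SHARC) pairwise correlation
    structure while conserving per-frame population counts and per-neuron
    activity budgets, decodes behavior with a single-hidden-layer
    random-projection classifier trained by a delta rule, extracts
    classifier-derived neuronal ensembles, and scores the behavioral
    specificity of three-neuron coactivity combinations against swap-shuffled
    null distributions. Includes a synthetic two-state raster generator
    (correlation-coded and rate-coded) so the full pipeline is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    signal,
    glmnet,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
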