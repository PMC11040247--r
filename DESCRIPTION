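Package: noisybc
Title: Bounded-Confidence Opinion Dynamics with a Taxonomy of Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulator for the Deffuant bounded-confidence
    opinion model extended with four distinct types of noise: ambiguity
    (noisy messages), selectivity (noisy confidence bounds), adaptation
    (post-interaction opinion shifts) and exogenous (spontaneous opinion
    jumps).  Includes a survey-calibrated "six Americas" initializer for
    climate-change attitudes, disagreement metrics (dispersion, excess
    kurtosis, cluster counts, pro-environmental agreement), seeded
    ensemble drivers for (epsilon, nu) phase-diagram sweeps, critical
    noise estimation, and reproducible CSV/JSON result writers.  The
    stepping kernel is implemented in C++ for desk-scale Monte-Carlo
    ensembles; a pure-R single-step implementation of the identical
    update rules is provided for inspection and cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
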