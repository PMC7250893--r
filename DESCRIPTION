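Package: spatcv
Title: Causal Drivers of Fish Population Spatial Variability via
    Empirical Dynamic Modeling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify drivers of the spatial variability of surveyed
    fish populations.  Computes survey-derived time series from trawl-survey
    catch-per-unit-effort tables (spatial coefficient of variation, Shannon
    age diversity, total abundance), fits Taylor's power law, and implements
    empirical dynamic modeling from first principles: simplex projection for
    embedding-dimension selection, convergent cross mapping with a replicated
    convergence protocol and lag scanning, and the multivariate S-map
    estimator of time-varying interaction strengths.  Includes an
    age-structured spatial survey simulator with known causal structure for
    validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
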