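Package: hybridevap
Title: Hybrid Process-Based and Learned Modelling of Terrestrial Evaporation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Daily terrestrial evaporation modelling with a process-based
    host (multi-layer soil water balance and Priestley-Taylor potential
    evaporation) bidirectionally coupled to a learned transpiration-stress
    function. A small feed-forward network maps absolute values and seasonal
    anomalies of plant-available water, vapour pressure deficit, air
    temperature, shortwave radiation, vegetation optical depth and CO2 to a
    stress factor in [0,1], trained by minimising 1 - KGE (Kling-Gupta
    efficiency). Includes flux-tower and sap-flow style training-table
    preparation (rain-day filtering, LAI-based transpiration partitioning,
    crown-area allometric upscaling, potential-transpiration bias
    correction), a seeded synthetic-world generator with a known
    ground-truth stress function for end-to-end validation, KGE-based
    evaluation utilities, and a configurable pipeline with a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
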