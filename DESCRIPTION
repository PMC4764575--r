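Package: kinetoswitch
Title: Sister Kinetochore Directional Switching Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and Bayesian inference for metaphase sister-kinetochore
    oscillations. Implements a Markov-switching linear autoregressive model of
    paired kinetochore motion along the metaphase-plate normal, Gibbs and
    Metropolis-Hastings sampling of model parameters and hidden polymerisation
    states, detection and classification of directional switching events
    (lead-initiated, trail-initiated and joint), metaphase-plate coordinate
    geometry (inter-sister distance, percent stretch, twist angle), and
    event-aligned and run-rescaled trajectory averaging with the associated
    rank-based cohort statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
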