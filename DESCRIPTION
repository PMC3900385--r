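Package: analogspike
Title: Information and Energy Costs of Converting Graded Potentials to
    Action Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantifying the
    information loss and energy-efficiency drop that accompany the
    conversion of graded (analogue) neuronal potentials into action
    potentials. Provides a stochastic single-compartment Hodgkin-Huxley
    model with exact Gillespie simulation of Markov ion-channel gating,
    band-limited Gaussian white-noise stimulus generation, direct-method
    spike-train entropy estimation with word-length extrapolation,
    Gaussian-channel information bounds for analogue responses, linear
    (Wiener) stimulus reconstruction with coherence-based information
    rates, action-potential footprint experiments, and ATP-based energy
    accounting from potassium fluxes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
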