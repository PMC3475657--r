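Package: gatingflux
Title: Probability Fluxes and Transition Paths in Ladder Models of Ligand-Gated Channel Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic relaxation analysis of reversible ladder-type Markov
    models of ligand-gated ion channels (such as the ten-state C4L-O4L scheme
    for HCN2 gating) after ligand concentration jumps. Computes occupancy time
    courses by eigen-decomposition of the rate matrix, net and unidirectional
    probability-flux densities for every transition, time-integrated total net
    fluxes (spectral or Simpson quadrature), and a transition-path
    decomposition of the integrated flux graph into ranked source-to-sink
    pathway fluxes with producer/collector classification and a hysteresis
    index comparing activation and deactivation. Ships a detailed-balance
    preserving synthetic model generator and an exact stochastic (Gillespie)
    ensemble simulator used as an independent oracle for every deterministic
    quantity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
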