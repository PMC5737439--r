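Package: pelotonr
Title: Stochastic Traffic of RNA Polymerases Through Dynamic Nucleosome Roadblocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Kinetic Monte-Carlo simulation and closed-form theory for molecular
    motors (RNA polymerase II) translocating through dynamically rebinding
    roadblocks (nucleosomes) on a one-dimensional lattice. Implements the
    motor-roadblock exclusion process (a footprint-generalized Bus-Route
    Model), an exact event-driven simulator with open or periodic boundaries,
    analytic predictions for peloton size, peloton formation distance,
    density and velocity profiles, and the mapping of elongation-generated
    transcriptional bursts onto the two-state (telegraph) promoter model.
    Observable extraction covers gap-size distributions with geometric
    mixture fits, peloton identification, position-resolved density and
    velocity profiles, relaxation-length fits, and burst statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    minpack.lm,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
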