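Package: somnet
Title: Thalamocortical Network Model of Sleep Stages Under Neuromodulatory Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Conductance-based thalamocortical network model in which three
    neuromodulator variables (acetylcholine, histamine and GABA) scale
    potassium-leak, AMPA, GABA-A and h-current properties to produce the
    electrographic signatures of wake, N2 (sleep spindles), N3 (slow
    oscillation) and REM sleep. Includes two-compartment cortical pyramidal
    and interneuron models, single-compartment thalamocortical relay and
    reticular neurons with calcium-gated h-current kinetics, kinetic synapse
    models with miniature PSPs and short-term depression, a fast compiled
    network integrator, stage schedules and experiment presets (minimal
    models, propofol anesthesia, tonic GABA variants), and a signal-analysis
    chain: simulated LFP, band power, phase-locking value, spindle and
    slow-oscillation event detection, and Gaussian-mixture regime clustering
    with AIC model selection projected into neuromodulator space.
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
    ggplot2,
    rlang,
    generics,
    signal,
    mclust,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
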