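Package: memcortex
Title: Memristive Synapse Plasticity and BCM Development of Binocular
    Orientation Selectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for an artificial striate cortex built from
    optically driven memristive synapses. Provides a phenomenological
    second-order memristor model (conductance window, paired-pulse
    facilitation, potentiation/depression nonlinearity, frequency- and
    history-dependent plasticity), pair- and triplet spike-timing-dependent
    plasticity kernels with all-to-all accumulation and first-spike
    suppression, the rate-based Bienenstock-Cooper-Munro (BCM) learning rule
    with a sliding modification threshold, Poisson rate-coded stimulus
    generators emulating a solar-cell optical front end, and network-level
    experiments: crossbar pattern learning and two-eye orientation-selectivity
    development under normal rearing, monocular deprivation and binocular
    deprivation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
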