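Package: bgspike
Title: Spiking Basal Ganglia Network Model of Synchrony, Exploration and
    Action Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the subthalamic nucleus (STN), globus pallidus
    externa (GPe) and interna (GPi) as 2D lattices of Izhikevich spiking
    neurons coupled by AMPA, NMDA and GABA synapses with
    dopamine-modulated lateral kernels and projection weights. Striatal
    input is modeled as Poisson spike pools. Provides spike-phase
    (Kuramoto-type) synchrony analysis, firing-rate and population
    oscillation metrics, race-model action selection with
    Go/Explore/No-Go classification, a binary action selection task and
    a restless four-armed bandit task in which the reward prediction
    error drives dopamine and cortico-striatal plasticity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
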