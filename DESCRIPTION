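Package: lsanet
Title: Learning by Stimulation Avoidance in Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for learning by stimulation avoidance (LSA) in Izhikevich
    spiking neural networks. Provides millisecond-resolution network dynamics with
    additive spike-timing-dependent plasticity (STDP), multiplicative weight decay,
    and Tsodyks-Markram-style short-term plasticity for burst suppression;
    closed-loop stimulation protocols (stop and stimulus conditions) reproducing
    selective learning, synaptic reinforcement and pruning in minimal three-neuron
    circuits, firing-rate steering in sparse networks, connectivity parameter
    sweeps, and an embodied wall-avoidance task in which a simulated robot is
    controlled by a spiking network. Results are returned as tibbles with broom-style
    tidiers and ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    arrow
Config/testthat/edition: 3
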