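Package: spikecart
Title: Spiking Neuronal Network Agents for the CartPole Control Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulation of a three-layer excitatory/inhibitory
    spiking neuronal network that learns to balance the classic cart-pole.
    Provides the reduced integrate-and-fire neuron model with adaptation,
    refractoriness and depolarization block; seeded construction of the
    sensory-association-motor network; a population-coded sensory encoder and
    winner-take-all motor decoder; a hand-crafted critic; spike-timing
    dependent reinforcement learning with eligibility traces, targeted
    delivery variants and synaptic homeostasis; a multiplicative evolutionary
    strategy over the plastic-weight genome; and post-training circuit
    dissection (all-inputs sweeps, action-selectivity and sensory-motor maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
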