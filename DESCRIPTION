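Package: sornsp
Title: Self-Organizing Recurrent Spiking Networks with Structural Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of reward-modulated self-organizing
    recurrent networks of binary spiking neurons. The recurrent layer is
    shaped by reward-modulated spike-timing-dependent plasticity with
    eligibility traces, homeostatic plasticity (synaptic normalization and
    intrinsic threshold plasticity), and structural plasticity (stochastic
    synapse growth and weight-threshold pruning). Includes three periodic
    sequence-learning benchmarks (counting, motion prediction, motion
    generation), a two-stage alternating training protocol, evaluation
    metrics, and statistical analyses of the emergent connectivity:
    lognormal weight distributions, power-law synapse lifetimes, and
    survival of strong connections.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    fitdistrplus
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
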