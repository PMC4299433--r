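Package: plastisim
Title: Spiking Network Simulation with Batched Synaptic Plasticity
Version: 0.1.0
Authors@R:
    person("plastisim", "developers", email = "plastisim@example.org",
           role = c("aut", "cre"))
Description: Discrete-time (1 ms) simulation of leaky integrate-and-fire
    networks in which synaptic plasticity is computed in batched passes over
    the weight matrix every 128 ms, driven by double-buffered 2 ms
    spike-history bitmaps, rather than synapse-by-synapse at spike events.
    Implements three weight-update rules operating on the windowed spike
    history: all-to-all trace-based STDP, the rate-based BCM rule with a
    sliding modification threshold, and a voltage-gated bistable STDP rule
    with a calcium eligibility trace. Includes generators for classical
    stimulation protocols (Poisson sources, teacher bursts, oriented bars,
    tonotopic frequency sweeps), scripted reproductions of classical learning
    experiments (latency reduction, weight bimodality through synaptic
    competition, emergence of orientation selectivity, temporal-pattern
    learning through delay lines), a JSON configuration front end and a small
    command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
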