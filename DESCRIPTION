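Package: SpikeDynamics
Title: Temporal Signatures and Metastable Dynamics of Frontal Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to extract the temporal signature (autocorrelogram peak
    latency LAT and decay time constant TAU) of single-unit spike trains, to
    simulate conductance-based single neurons and recurrent
    excitatory/inhibitory networks with CAN/AHP intrinsic currents and
    AMPA/NMDA/GABA-A/GABA-B synapses, to segment population spiking into
    metastable states with Bernoulli-emission hidden Markov models, and to
    probe state stability with a targeted state-substitution perturbation
    protocol. Includes seeded synthetic-data generators (OU-rate Poisson
    trains, gamma-renewal/burst trains, Markov-switching rasters, session
    event logs) so every analysis stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    minpack.lm,
    MASS
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
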