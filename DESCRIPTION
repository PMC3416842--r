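Package: mixnet
Title: Mixed-Synapse Attractor Neural Networks: Associative Memory and
    Sequence Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulator and mean-field phase-diagram solver for
    Hopfield-type attractor neural networks whose synaptic matrix is a
    weighted mixture of a symmetric (associative memory) and an asymmetric
    (sequential pattern recognition) Hebbian part.  Supports the classical
    single-pattern-set mixture as well as the two-independent-set variant in
    which fixed-point and cyclic attractors coexist.  Implements parallel
    Glauber dynamics at finite temperature, random dilution of the coupling
    matrix, retrieval protocols for both dynamics, the stationary
    order-parameter equations of all four model/dynamics combinations, their
    spin-glass transition temperatures, zero-temperature storage capacities,
    and phase-region classification over load and temperature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
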