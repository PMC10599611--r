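Package: ringmelt
Title: QUBO Encoding and Sampling of Self-Assembled Lattice Ring-Polymer Melts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Encodes self-assembly of ring polymers on cuboid simple-cubic
    lattices as a quadratic unconstrained binary optimization (QUBO) problem
    whose degenerate zero-energy ground states are exactly the valid melt
    microstates, with optional quadratic constraints fixing total curvature
    (corner turns) and compactness (contacts). Ground states are sampled by
    a built-in simulated annealer, decoded into explicit ring configurations,
    and analysed for melt observables including exact pairwise Gaussian
    linking numbers. Includes an exhaustive ground-state enumerator for tiny
    lattices, a real-space plaquette-flip replica-exchange Monte Carlo
    baseline for fully packed melts, and campaign utilities for ensemble
    statistics, power-law and exponential-decay fits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
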