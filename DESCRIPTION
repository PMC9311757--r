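Package: porinflux
Type: Package
Title: Channel Permeation Currents and Conformational Descriptors from
    Free-Energy Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-simulation analysis for small-molecule permeation through
    bacterial porins. Computes per-conformer size and dipole descriptors
    (minimal projection area, minimum radius, total and transversal dipole
    moment) from solution ensembles, reduces two-dimensional metadynamics
    free-energy surfaces over (orientation, z) to one-dimensional potentials
    of mean force by Boltzmann averaging, and predicts translocation
    currents, saturation and dwell times with a Kramers-type permeability
    integral coupled to a single-occupancy two-state Markov channel model.
    Includes a synthetic-data generator with analytic ground truth, a
    finite-difference Smoluchowski solver and a continuous-time Markov-chain
    simulator as internal brute-force oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    pracma,
    jsonlite,
    yaml,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
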