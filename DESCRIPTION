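Package: ecmigrate
Title: Particle-Based Simulation of Endothelial Cell Migration Under Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of endothelial cell migration on the wall
    of a perfused channel. Cells are particles that adhere to each other and to
    the substrate through a truncated Lennard-Jones / soft-core contact force,
    perform persistent random walks whose direction is biased by the local
    flow velocity, and are confined to a monolayer band above obstacle
    lattices representing the substrate, ridges (stent struts) and a
    backward-facing step. A built-in D2Q9 lattice-Boltzmann solver supplies
    steady channel flow fields, with wall shear stress and recirculation-zone
    diagnostics. Includes end-to-end scenario runners (flat calibration,
    ridged channel, ROCK inhibition, backward step), trajectory analysis
    (angular and axial distributions, migration speed, entrapment) and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
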