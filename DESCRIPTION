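Package: rigidlink
Title: Dual-Trap Optical Tweezer Simulation and Analysis with Rigid DNA Beam Linkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the stiffness of molecular linkers sets the
    resolution of dual-trap optical tweezer experiments. Provides closed-form
    polymer elasticity models (worm-like chain, extensible worm-like chain,
    extensible freely-jointed chain) and their series composition; a Metropolis
    Monte-Carlo simulator of two beads in 3D harmonic traps connected by a
    tether, with force-ramp and constant-trap-distance protocols and an
    optional two-state DNA hairpin; trace post-processing (moving-window noise
    profiles, apparent stiffness, bead-contact detection); two-state kinetics
    by dwell-time analysis and Gaussian hidden-Markov modelling; free-energy
    landscape reconstruction by constrained iterative deconvolution of
    deflection histograms against an empirical point-spread function; and
    semiflexible-beam shape statistics for estimating bundle persistence
    lengths from traced 2D backbones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
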