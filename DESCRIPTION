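Package: hydrotrap
Title: Hydrodynamic Trapping Analysis of Membrane-Anchored Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the lateral chemical potential and effective dimensions
    of molecules anchored in a supported lipid bilayer from hydrodynamic
    trapping experiments, in which the focused flow from a micropipette
    accumulates the molecules against their own repulsion. Implements the
    two-dimensional hard-disk virial thermodynamics, the empirical
    hydrodynamic-area model for surface-grafted cylinders and its inversion
    to an effective height, the full inference chain from trap images to
    interaction curves and excess chemical potentials, and a compiled
    Metropolis Monte Carlo engine with Widom insertion for surface-grafted
    bead-chain molecules with tilt restraints and glycan decorations. A
    synthetic-data generator produces steady-state trap images from known
    ground truth so that every stage of the pipeline can be validated
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
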