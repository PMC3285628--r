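Package: polarisim
Title: Bistable Reaction-Diffusion Modelling of Cell Membrane Polarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for cell-membrane polarization
    driven by local enzymatic bistability and cytosolic enzyme shuttling.
    A pair of interconverting membrane-bound signaling species is switched
    by two counteracting enzymes recruited from a shared well-mixed
    cytosolic reservoir, producing Goldbeter-Koshland ultrasensitivity with
    reinforcing feedback.  The package reduces the dynamics to a single
    activated fraction with an effective potential, computes the phase
    diagram (bistability region, phase-coexistence line, equilibrium patch
    areas), integrates the deterministic mean-field equations on a
    triangulated spherical membrane with a cotangent finite-element
    Laplace-Beltrami operator, runs exact Gillespie simulations of the
    underlying lattice master equation with an integer cytosolic reservoir,
    and ships scenario presets for eukaryotic chemotaxis, epithelial
    polarization, budding yeast and Ras signaling domains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    deSolve,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
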