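Package: tubelattice
Title: Locally Ordered Lattice Reconstruction on Membrane Nanotubes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cryo-EM image processing for protein lattices that decorate lipid
    nanotubes with only local (not global helical) order. Provides a synthetic
    decorated-nanotube forward model with stacked and relaxed lattice states,
    per-particle tube alignment and membrane-peak diameter measurement,
    azimuthal-average initial models, region-of-interest signal subtraction
    (RASTR), constrained projection-matching refinement with Fourier shell
    correlation, helical lattice parameter estimation, 2D classification with
    stacked-state scoring, and sub-particle extraction and reconstruction at
    model-derived membrane-contact coordinates. Volumes and image stacks use
    the MRC format; particle metadata uses STAR tables with RELION-style
    column names.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
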