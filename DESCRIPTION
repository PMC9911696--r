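Package: rnatopo
Title: Recapitulating RNA 3D Topology from AFM Molecular Surfaces with
    SAXS and ITC Corroboration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recovers coarse-grained three-dimensional topological models of
    folded RNA from atomic force microscopy (AFM) height images.  Builds
    two-bead-per-nucleotide models from sequence and dot-bracket secondary
    structure with ideal A-form duplexes, renders simulated AFM molecular
    surfaces with a spherical-tip contact model, and runs simulated-annealing
    Monte-Carlo dynamic fitting that couples an image cross-correlation
    pseudopotential to covalent and noncovalent coarse-grained energies.
    Conformational ensembles are corroborated by small-angle X-ray scattering
    (Debye profiles, simplex-constrained volume-fraction fitting, Guinier,
    P(r) and correlation-volume analysis) and by singular-value-decomposition
    deconvolution of isothermal titration calorimetry thermograms with one-
    and two-site Wiseman isotherm fits selected by F-test.  A synthetic-data
    generator produces ground-truth phantoms, noise ladders, scattering
    mixtures and two-component thermograms for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    minpack.lm,
    deSolve,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
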