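Package: perifem
Title: Voxel-Based Micro-Finite-Element Analysis of Peri-Implant Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic labelled specimens of implanted mandibular
    bone with and without explicit trabecular microstructure, emulates
    micro-CT and cone-beam CT intensity volumes from them, recovers bone and
    implant labels by discriminant (Otsu) thresholding and seeded graph-cut
    refinement, converts label maps into 8-node hexahedral micro-finite-element
    models (one element per voxel), solves the small-strain linear-elastic
    load case with a Jacobi-preconditioned conjugate-gradient solver, and
    summarizes equivalent, tensile and compressive stress and strain at the
    implant-bone interface, including the paired comparison between the
    microstructural (refined) and homogenized (simplified) models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png,
    optparse,
    yaml
Config/testthat/edition: 3
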