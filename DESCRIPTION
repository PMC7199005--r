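Package: ritomo
Title: Compartment Segmentation and Dry-Mass Morphometry for Refractive-Index Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of 3D refractive-index (RI) tomograms
    from optical diffraction tomography / holotomography of living cells.
    Segments subcellular compartments by RI bands (closed intervals), separates
    in-band "colour" volume from the filled enclosed volume, and computes a full
    morphometric panel per compartment: volume, isosurface area, projected area,
    mean RI, dry-mass concentration via the Barer refractive-increment relation,
    dry mass, and Wadell sphericity. Includes readers and writers for multi-page
    float TIFF stacks and HDF5 containers with voxel-spacing metadata, and a
    synthetic phantom generator (calibration bead and four-compartment
    diatom-like cell with anisotropic optical blur and noise) with voxel-level
    ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rhdf5,
    rlang,
    tibble,
    tidyr,
    tiff,
    tools,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
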