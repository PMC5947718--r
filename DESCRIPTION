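Package: esttomo
Title: Equally Sloped Tomography and Dual-Energy Absorption-Edge Mapping
    for Scanning X-ray Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstruction and analysis pipeline for dual-energy scanning
    transmission X-ray microscopy (STXM) tomography of whole cells. Implements
    the pseudo-polar fast Fourier transform with equally sloped angle sets, an
    iterative equally-sloped-tomography (EST) reconstruction that handles
    missing-wedge tilt series, centre-of-mass tilt alignment, above/below
    absorption-edge volume differencing for three-dimensional elemental
    mapping and quantification, absorption-based organelle segmentation, and a
    synthetic macrophage phantom generator with a Beer-Lambert/Poisson tilt
    series simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    igraph,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: fftw3
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
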