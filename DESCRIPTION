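Package: multitilt
Title: Multi-Tilt Electron Tomography: Simulation, Fiducial Alignment and
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for n-fold multi-tilt electron tomography of plastic
    sections: simulation of tilt-series acquisition with gold-bead phantoms
    and dose-dependent specimen compression, automatic fiducial detection and
    multi-series track building, simultaneous bundle adjustment of polynomial
    projection maps with deformation monitoring, filtered back-projection and
    weighted-SIRT reconstruction, and closed-form plus Monte-Carlo analysis of
    missing Fourier-space coverage for multi-axis tilt schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
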