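Package: kwia
Title: K-Space Weighted Image Average Reconstruction for Low-Dose CT Perfusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for low-dose dynamic CT
    perfusion. Provides dynamic digital phantoms (a FORBILD-style head with
    time-varying vessels and a rod-based perfusion phantom), parallel-beam
    forward projection and fan-beam rebinning, Poisson low-dose sinogram
    simulation with variance-matched dose-reduction injection, view-shared
    k-space ring averaging (KWIA) reconstruction via Voronoi density
    compensation and Kaiser-Bessel regridding, filtered back projection
    baselines, image-quality metrics (SNR, CNR, Bland-Altman), and perfusion
    quantification with time-density curves and truncated-SVD deconvolution
    of cerebral blood flow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
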