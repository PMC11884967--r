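Package: bcars
Title: Simulation and Analysis of Broadband CARS Hyperspectral Single-Cell Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for broadband coherent anti-Stokes Raman
    scattering (BCARS) hyperspectral single-cell classification: cosmic-ray
    despiking, truncated-SVD denoising with Fourier-based singular-vector
    selection, Kramers-Kronig nonresonant-background removal with
    asymmetric-least-squares phase and amplitude error correction,
    segmentation-driven per-cell spectral averaging, extended multiplicative
    signal correction, and random-forest classification with mixture
    evaluation. Includes a physics-based synthetic scene generator (complex
    third-order susceptibility forward model) that provides ground truth for
    every stage, so the whole workflow is verifiable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ranger,
    EBImage,
    MASS,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
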