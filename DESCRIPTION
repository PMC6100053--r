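Package: thztds
Title: Terahertz Time-Domain Spectral Analysis of Molecular Fingerprints
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for transmission terahertz time-domain
    spectroscopy (THz-TDS) of crystalline powders such as pesticide pellets.
    Extracts absorption coefficient and refractive index spectra from paired
    reference/sample time traces via the thick-slab Fresnel transmission
    model, removes spectral noise by Daubechies-5 wavelet soft-threshold
    de-noising scored with PSNR/RMSE, corrects baseline drift by asymmetric
    least squares smoothing, detects absorption peaks with anomalous
    dispersion confirmation, and matches experimental peaks to theoretical
    (DFT-computed) line tables with signed frequency shifts. Includes a
    Lorentz-oscillator forward simulator of the measurement so the full
    chain is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
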