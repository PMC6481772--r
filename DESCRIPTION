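Package: fastMNF
Title: Fast Minimum Noise Fraction Denoising for Hyperspectral Chemical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Denoising of hyperspectral chemical images (e.g. FTIR
    spectroscopic images of tissue) with the Minimum Noise Fraction (MNF)
    transform.  Provides fully automated band selection via the Rose
    criterion (SNR >= 5), three accelerated transform variants (Fast,
    Approx via block-Krylov truncated eigendecomposition, Rand via
    randomized sketch SVD), shift-difference noise covariance estimation,
    ENVI-format cube input/output, a synthetic FTIR-like cube generator
    with known ground truth, and no-reference denoising quality metrics
    (SSIM maps and the method-noise-image correlation score).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
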