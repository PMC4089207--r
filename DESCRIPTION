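Package: despecklr
Title: Structure-Based Despeckling of Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Speckle reduction for ultrasound (and other coherently imaged)
    grayscale images by per-pixel structure analysis. The Hessian of image
    intensity is computed at a Gaussian scale, its eigensystem classifies
    each pixel as uniform, linear (bright ridge), boundary (dark valley),
    spot, or unknown, a refinement pass repairs broken curvilinear
    structures, and a type-driven filter pool (oriented 1D Gaussian stick,
    2D median, 2D Gaussian) smooths speckle while preserving and enhancing
    edges, iterated over multiple passes. Includes multiplicative
    Rayleigh-type speckle simulation, PSNR/SSIM quality metrics, baseline
    filters, a labeled synthetic phantom generator, and a benchmark
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
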