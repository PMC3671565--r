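Package: sarclen
Title: Subpixel Sarcomere Length Estimation from Striation Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates the mean sarcomere length of striated muscle cells
    from microscopy images as the fundamental spatial period of the
    striation pattern, at subpixel resolution.  The central estimator is a
    finite-extent least-squares similarity measure that, under a
    piecewise-linear model of the image line, is an exact piecewise cubic
    polynomial of the shift and is minimised in closed form; it is free of
    the boundary bias that affects autocorrelation- and Fourier-based
    period estimators, which are provided as baselines.  Includes an
    envelope-midpoint detrending preprocessor, rotated region-of-interest
    extraction with orientation correction, sensitivity maps, per-frame
    contraction tracing with shortening rates, synthetic striation-image
    generators with known ground truth, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
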