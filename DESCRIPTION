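Package: voxfilt
Title: Temporal Super-Resolution Receptive Fields from Slowly Sampled Neural Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates temporal receptive fields (linear filters) at the
    resolution of a rapidly updated stimulus from neural responses that are
    sampled infrequently but at precisely known times, as in scanning
    two-photon or volumetric imaging. Pairs each response sample with the
    exact stimulus history preceding it, then fits filters by
    cross-correlation, ordinary least squares, discrete-Laguerre-basis
    regression, or automatic smoothness determination (ASD), and computes
    response-weighted stimulus covariance for second-order receptive fields.
    Includes interpolation baselines, kernel smoothing with a triangle-filter
    correspondence to linear interpolation, a synthetic-experiment generator,
    scan-geometry timing utilities, dF/F baselining, bias-corrected bootstrap
    uncertainty, and volumetric versus plane-by-plane sampling-design
    comparisons.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
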