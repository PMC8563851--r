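Package: furaSE
Title: Standard Errors for the Ratiometric (Fura-2) Calcium Estimator
Version: 0.1.0
Authors@R:
    person("furaSE", "Maintainers", email = "furase@example.org",
           role = c("aut", "cre"))
Description: Attaches standard errors to free-calcium concentration estimates
    obtained from two-wavelength (340/380 nm) Fura-2 fluorescence recordings.
    Starting from raw camera counts in a region of interest and a background
    region, the package models CCD shot and read-out noise, propagates the
    resulting uncertainty through background subtraction, the fluorescence
    ratio and the ratiometric calcium transform - both by first-order
    propagation of uncertainty (delta method) and by a per-time-point
    Monte-Carlo scheme. A forward simulator generates synthetic transients
    from a known calcium time course, and a validation pipeline checks that
    normalized residuals are standard normal (Shapiro-Wilk test, empirical
    CDF against Kolmogorov confidence bands) and supports weighted
    monoexponential decay fits with honest parameter uncertainties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
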