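Package: survband
Title: Simultaneous Confidence Bands for Kaplan-Meier Survival Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simultaneous confidence bands for right-censored survival
    curves estimated by the Kaplan-Meier product-limit method.  Implements
    the Gill, Hall-Wellner and Nair equal-precision bands with linear,
    log and arcsine-square-root transformations, Thomas-Grunkemeier
    nonparametric likelihood-ratio intervals and the Hollander-type
    simultaneous likelihood-ratio band, and Akritas bootstrap calibration
    of the Hall-Wellner critical value.  Critical values for the suprema
    of the limiting Brownian motion and Brownian bridge processes are
    computed directly (series, numerical integration and Monte Carlo), so
    any confidence level may be used.  A coverage-simulation harness
    quantifies the difference between simultaneous and naive pointwise
    coverage under right censoring.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
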