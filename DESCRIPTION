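Package: shrubmass
Title: Two-Component Allometric Estimation of Tall-Shrub Biomass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates tall-shrub wet field-mass from stem diameters using
    self-similar power-function allometry for aerial tips, conic-frustum
    volume times wet wood density for large stem internodes, and Monte-Carlo
    propagation of lognormal prediction error from individual components to
    plot-level 95 percent intervals. Includes the sampling-design decision
    rule that selects the diameter threshold above which stems should be
    measured as frustra, balancing the expected gain in precision against
    the extra measurement time, plus a synthetic-shrub simulator for
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
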