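Package: fracrisk
Title: Fraction-Based Ecological Risk Assessment of Soil Heavy Metals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and probabilistic ecological risk assessment of
    soil heavy metals from BCR sequential-extraction fractions. Implements
    the geoaccumulation index, the classic Hakanson potential ecological
    risk index, a fraction-weighted (modified) Hakanson index with
    re-derived grading thresholds, and a Monte Carlo extension that fits
    normal or lognormal distributions to corrected concentrations
    (Shapiro-Wilk selection with boxplot outlier screening), propagates
    them to single (Er) and comprehensive (RI) hazard indices, and reports
    risk-class probabilities, cumulative distributions, and
    contribution-to-variance sensitivities. Includes descriptive screening
    tools (coefficient of variation, background exceedance rates, fraction
    profiles, correlation screens against soil physicochemical properties)
    and a synthetic study generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
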