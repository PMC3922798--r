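Package: pmcalib
Title: Calibration Coefficients for Surrogate PM2.5 Exposures in Multi-City
    Panel Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates regression-calibration coefficients relating "true"
    personal fine-particle (PM2.5) exposures -- personal PM2.5 of ambient
    origin via the sulfate tracer method, or total personal PM2.5 -- to the
    surrogate exposures used in long-term epidemiologic studies
    (nearest-monitor ambient concentrations and outdoor-home model
    predictions). Fits hierarchical linear mixed models with city and subject
    random intercepts and a city random slope by restricted maximum
    likelihood, tests between-city heterogeneity of the calibration
    coefficient with a boundary-corrected 50:50 mixture likelihood-ratio
    test, explains heterogeneity with stepwise city-covariate meta-regression,
    and validates the selection by leave-one-city-out cross-validation.
    Includes a synthetic multi-city panel generator with known ground truth
    so the full pipeline is testable without access to personal-monitoring
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
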