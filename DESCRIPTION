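Package: coldsnap
Title: Cold-Weather Mortality Risk Estimation for Small Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cold-related winter mortality at small-area
    level from daily weather-station temperatures and daily death counts.
    Builds composite area temperature series with coverage filtering and
    seasonal imputation, fits threshold distributed-lag quasi-Poisson models
    (effect null above a cold threshold, linear in cold excess below it,
    distributed over lags 0-28 within independent winter series), and derives
    cumulative relative risks between two temperatures, attributable deaths and
    fractions under a counterfactual reference temperature, pre/post
    intervention comparisons, between-area I-squared heterogeneity, and a
    fuel-poverty-based unmet-need classification. Includes a synthetic-data
    generator with known exposure-lag-response ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    splines,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
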