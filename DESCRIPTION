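Package: devgraph
Title: Deviation-Value Profiling of Country Nutrition and Health Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes country-level deviation values (T-scores, mean 50,
    standard deviation 10) for nutrition- and health-related indicators to
    diagnose the double burden of malnutrition. Each indicator's
    cross-country distribution is normalized with a Box-Cox power
    transformation before standardization; indicators compressed against a
    ceiling (e.g. near-100 percent literacy) are scored by rank-percentile
    mapping to normal quantiles instead. Scores are oriented so that higher
    always means more desirable, classified by distribution modality
    (normal, distorted, bimodal, trimodal), stratified by World Bank income
    class, and assembled into per-country life-stage profiles rendered as
    deviation graphs. A synthetic-data generator reproduces the
    distributional shapes the method must handle, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    mclust,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
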