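Package: expozone
Title: Mortality-Risk Regionalization from Pollution-Exposure Suitability Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regionalizing mortality risk from environmental
    pollution. Screens causes of death by mortality-rate ratio against a
    reference series, fits a presence-background maximum-entropy suitability
    model over pollution-factor rasters (distance to rivers, distance to
    industries, fine particulate matter, elevation), classifies the fitted
    suitability surface into exposure zones by exact Fisher-Jenks natural
    breaks, and quantifies disease-exposure association per zone with odds
    ratios, Woolf confidence intervals, relative risk, and the attributable
    fraction in the exposed. Includes a synthetic-region simulator with
    planted exposure-disease effects so the whole pipeline is testable
    without undeposited registry or satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
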