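Package: pppscore
Title: Potential Propagule Pressure Scoring for Vessel Inspection
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Proxy-based scoring of commercial vessel arrivals for marine
    biosecurity inspection prioritization. Estimates each arrival's total
    wetted surface area from gross tonnage via vessel-type power-law
    regressions (with a direct hull-form calculation for barges and
    articulated tug-barges), combines it with reported ballast water
    discharge volume into a median-normalized potential propagule pressure
    (PPP) score, and produces daily inspection priority lists under a
    capacity constraint as well as cumulative scores by port, vessel type,
    or time period. Includes a synthetic multi-year fleet generator for
    testing and calibration, delimited-text input/output with schema
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
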