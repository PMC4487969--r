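Package: huttrial
Title: Entomological Endpoints and Simulation for Experimental Hut Trials of
    Insecticide-Treated Nets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for WHOPES Phase-II experimental hut trials of
    insecticide-treated mosquito nets. Computes the six standard entomological
    endpoints (deterrence, induced exiting, control-corrected mortality,
    overall killing effect, blood-feeding inhibition, personal protection)
    from per-hut-night collection records; determines the wash-resistance
    cut-off ("point of insecticide exhaustion") from serial cone bioassays;
    summarises tunnel tests and insecticide retention; performs arm-wise
    comparisons of proportions (logistic regression) and nightly counts
    (negative-binomial regression) with compact-letter significance
    groupings; generates and validates Latin-square rotation plans; and
    simulates complete hut-trial datasets with known generative parameters
    for end-to-end testing and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    jsonlite,
    MASS,
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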