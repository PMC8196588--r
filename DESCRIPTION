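Package: tomachem
Title: Chemometric Calibration of Tomatine Content from Thermogravimetric
    and Mid-Infrared Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two calibration routes for predicting the glycoalkaloid tomatine
    (alpha-tomatine plus dehydrotomatine, mg/kg dry weight) in tomato samples.
    The first regresses log10 tomatine on two thermogravimetric weight-loss
    features through a zero-intercept multiple linear regression with full
    inference statistics. The second is a chemometric pipeline for ATR
    mid-infrared spectra: standard normal variate scaling, Savitzky-Golay
    second-derivative filtering, mean centering, single-response kernel
    partial least squares with venetian-blinds cross-validation, and
    jackknife-based uncertainty-test variable selection. Printed reference
    tables ship as fixtures and synthetic generators emulate both data types
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
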