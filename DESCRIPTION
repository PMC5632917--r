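Package: airadmit
Title: Acute Air-Pollution Effects on Elderly Asthma Hospital Admissions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for estimating acute effects of ambient air pollution on
    daily elderly asthma hospital admissions from linked daily time series.
    Implements single-pollutant Poisson time-series regression with natural
    cubic spline temperature adjustment and day-of-week indicators across
    lag-window moving averages (percent increase per 10 ug/m3 with Wald
    confidence intervals); Lorenz-curve discretization of daily admission
    counts into low/high admission states; odds-ratio grid search over
    threshold-exceedance indices to select a binary pollution-severity
    indicator; and severity-stratified two-state Markov transition
    probability estimation with block-bootstrap uncertainty. A synthetic
    daily-series generator with known ground truth supports parameter
    recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
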