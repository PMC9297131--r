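Package: searchcycles
Title: Diurnal and Day-of-Week Rhythm Analysis for Hourly Search-Interest Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and summarising diurnal and day-of-week cyclic
    patterns in hourly relative-search-volume (RSV) time series such as Google
    Trends Historical Hourly Interest data. Implements Serfling-type harmonic
    regression with an orthogonal cubic trend, separate weekday and weekend
    diurnal harmonics, and an interval-indicator nuisance basis whose terms are
    selected by cross-validated LASSO to filter epidemics and other localized
    outliers. Fitted diurnal curves are summarised by circular median peak
    times, amplitude-to-mean ratios and a weekday-weekend cyclic-strength
    contrast, with standard errors, confidence intervals and P values from a
    fixed-width moving-block bootstrap. Includes a synthetic-data generator
    that emulates Trends-like hourly series with known ground truth, polar
    24-hour visualisations, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    methods,
    stats,
    utils,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
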