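Package: gaitrisk
Title: Daily-Life Gait Characteristics and Fall-Risk Modelling from Trunk Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether extreme values (10th and 90th
    percentiles) of daily-life gait characteristics predict falls in older
    adults better than their medians. Provides a synthetic generator for
    gait-like tri-axial trunk acceleration epochs and full cohorts with known
    generative structure; extraction of thirty gait characteristics per
    10-second epoch (spectral measures, harmonic ratio, index of harmonicity,
    stride regularity, sample entropy, local dynamic stability, and an
    inverted-pendulum gait-speed estimate); week-level percentile summaries
    with a running-epoch filter and between-week intraclass-correlation
    screening; univariate association scans and stepwise forward logistic
    fall-risk models with a Spearman collinearity screen, Hosmer-Lemeshow
    calibration and in-sample AUC; and a Monte Carlo block-permutation test
    for the significance of AUC improvement between nested models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
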