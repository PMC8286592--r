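Package: respirex
Title: Respiratory Pattern Features and Exercise Detection from Nasal-Pressure Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates labelled nasal-pressure recordings of the kind produced by
    oxygen-therapy telemonitoring devices, segments them into 45-second windows,
    detects breath cycles, and extracts four candidate feature families per window
    (breathing rate, inspiratory amplitude, ARIMA(1,1,1) coefficients and Fourier
    magnitudes below 2 Hz). Two classification frameworks compare the power of
    these features to discriminate rest from exercise: supervised mixed-effects
    logistic models and a per-subject one-class novelty detector based on the
    Mahalanobis distance, each evaluated by cross-validated ROC analysis with
    an upper-left-corner operating point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    lme4,
    glmmTMB,
    pROC,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
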