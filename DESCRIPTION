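Package: respgate
Title: Respiratory-Motion Prediction and Beam-Gating Control for MRI-Guided Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-specific online gating control for MRI-guided
    radiotherapy. Provides a synthetic quasi-periodic breathing-trace
    simulator, sliding-window dataset construction for multi-horizon
    forecasting, linear motion predictors (ordinary least squares, ridge
    with closed-form leave-one-out cross-validation, L2-L1 lasso solved
    by ADMM with generalized cross-validation, a constant-velocity
    Kalman-filter baseline, and an adaptive online variant with a
    burn-in period), linear-interpolated threshold-crossing time
    estimation, latency-compensated binary beam-gating signal
    generation, and amplitude and temporal accuracy metrics (MAE, RMSE,
    R-squared, crossing error, gating error, gating accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
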