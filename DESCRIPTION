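Package: crpredict
Title: Development and Internal-External Validation of Competing-Risks
    Prognostic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative framework for building and validating 10-year
    prognostic models under competing risks. Provides a synthetic cohort
    generator with Fine-Gray subdistribution structure, multi-region and
    two-period design and missing-at-random gaps; exact jackknife
    pseudo-observations of the Aalen-Johansen cumulative incidence and
    Kaplan-Meier failure functions; chained-equations multiple imputation
    with Rubin's-rules pooling and imputation stacking; four model-building
    strategies (Cox proportional hazards, pseudovalue complementary log-log
    regression, pseudovalue-target gradient boosting and a feed-forward
    neural network) with fractional-polynomial term selection and a
    magnitude-plus-significance predictor-selection rule; discrimination
    (Harrell's C, inverse-probability-of-censoring-weighted concordance),
    calibration (slope, calibration-in-the-large, smoothed pseudovalue
    calibration curves), decision-curve analysis under competing risks;
    and internal-external cross validation by region and period with
    Hartung-Knapp-Sidik-Jonkman random-effects meta-analysis, 95%
    prediction intervals and heterogeneity meta-regression.
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
    MASS,
    nnet,
    purrr,
    rlang,
    sandwich,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    cmprsk,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
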