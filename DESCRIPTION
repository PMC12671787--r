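Package: droughtfire
Title: Drought Characteristics and Geographically Weighted Logistic
    Models of Forest-Fire Occurrence Probability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling gridded forest-fire occurrence probability
    from multi-scale drought characteristics. Computes the Standardized
    Precipitation Evapotranspiration Index (SPEI) at 1-, 3-, 6- and 12-month
    scales from monthly temperature and precipitation via Thornthwaite
    potential evapotranspiration and probability-weighted-moment log-logistic
    standardization; identifies drought events by run theory and aggregates
    per-period duration, severity and intensity; assembles normalized
    covariates with collinearity diagnostics and reusable principal-component
    transforms; fits global and geographically weighted logistic regression
    with an adaptive bi-square kernel and AICc bandwidth selection; evaluates
    probability forecasts (ROC/AUC, Brier score, AICc); and projects
    probability changes under future climate scenarios. Includes a seeded
    synthetic-data generator so the full pipeline is exercisable without
    external downloads.
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
    geosphere,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
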