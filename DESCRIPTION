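Package: glycomediate
Title: Causal Mediation Analysis of Postprandial Glucose from Meal-Centered CGM Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the effect of meal carbohydrates on postprandial glucose
    excursions into an insulin-mediated component (ACME) and a direct component
    (ADE) using quasi-Bayesian causal mediation. Provides a synthetic CGM cohort
    generator with known ground-truth effects, meal-centered window construction
    with imputation and exclusion rules, a causally-constrained convolutional
    autoencoder that learns pre-treatment confounder embeddings under balancing,
    linearizability, conditional-independence and stability penalties,
    entropy-balancing weights for a continuous treatment with Kish
    effective-sample-size diagnostics, a left-censored Tobit mediator model, and
    mixed-effects and quantile-regression outcome models evaluated across
    postprandial horizons, dose contrasts, meal types and outcome quantiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    survival,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
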