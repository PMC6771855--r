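Package: plgfcea
Title: Within-Trial Cost-Effectiveness of Placental Growth Factor Testing
    for Suspected Pre-Eclampsia
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Economic evaluation toolkit for placental growth factor (PlGF)
    testing in women presenting with suspected pre-eclampsia, built around a
    stepped-wedge cluster-randomised trial design.  Provides a synthetic
    trial-data generator with centre random effects and a secular trend,
    two-part (hurdle) negative binomial mixed models for skewed healthcare
    resource use with AIC-based model selection and a logistic/linear
    fallback, activity-weighted NHS-reference-style unit costing, a
    probabilistic Monte Carlo cost model with beta-distributed maternal
    adverse events, cost-effectiveness acceptability curves, test-price
    sensitivity analysis, and national-scale extrapolation of per-woman
    savings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    glmmTMB,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
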