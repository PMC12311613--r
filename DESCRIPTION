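Package: lungrisk
Title: External Validation of Epidemiological Lung Cancer Risk Models
Version: 0.1.0
Authors@R: person("lungrisk", "maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for externally validating absolute-risk
    prediction models for lung cancer against screening eligibility
    criteria.  Ships a declarative registry of twelve published
    epidemiological risk calculators (logistic, Cox-baseline,
    relative-risk-times-incidence and annual competing-mortality
    recursion forms), boolean eligibility rules for the T/CPMA 013-2020,
    USPSTF-2021 and NELSON criteria, discrimination (AUC with DeLong
    intervals) and calibration (expected/observed ratios, risk-quartile
    bins) statistics, multiple imputation by chained equations with
    Rubin's-rules pooling, count-matched model-versus-criteria screening
    comparisons, and a synthetic cohort generator that reproduces a
    published cohort's stratified marginal structure by construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
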