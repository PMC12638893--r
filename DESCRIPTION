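Package: resil
Title: Residualized Stressor Reactivity and Positive Appraisal Style Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies stress resilience as residualized stressor reactivity
    (SR): internalizing-symptom scores are regressed on aggregated stressor
    exposure and each participant's deviation from the normative
    exposure-symptom line is their reactivity. Provides instrument scoring and
    reliability (Cronbach's alpha, two-occasion ICC), two exposure scoring
    dialects (z-score mean of life-event and daily-hassle counts; dichotomized
    sums), OLS and mixed-model normative lines with marginal/conditional R2,
    covariate-screened standardized-beta prediction models, bootstrap
    product-of-coefficients mediation with Monte-Carlo power analysis,
    counterfactual (natural-effects) mediation with chained-equation multiple
    imputation for two-arm trials, group-by-time intervention-effect models
    with estimated marginal means, and synthetic longitudinal cohort and RCT
    generators with planted effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
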