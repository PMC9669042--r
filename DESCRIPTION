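Package: hydroadvisor
Title: Personalized Plain-Water Intake Advice via Surrogate-Model Inversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts 24 h urine osmolality from anthropometric and intake
    features with gradient-boosted tree surrogates, then inverts the fitted
    surrogate under augmented-Lagrangian band constraints to recommend the
    daily plain-water intake that drives predicted urine osmolality to the
    500 mOsm/kg optimal-hydration target. Includes a mechanistic synthetic
    fluid-balance cohort generator (osmolar-clearance forward model),
    participant-grouped eligibility filtering and train/test splitting,
    partial-dependence/ICE and accumulated-local-effects model inspection,
    and contingency-table evaluation of the advice against EFSA
    adequate-intake baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    xgboost,
    ranger
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
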