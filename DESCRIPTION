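Package: navsurv
Title: Survival Impact Evaluation of Patient Navigation Programs with
    Propensity-Score (SMR) Weighting and Counterfactual Bootstrap
Version: 0.1.0
Authors@R:
    person("navsurv", "maintainers", email = "navsurv@example.org",
           role = c("aut", "cre"))
Description: Evaluates the overall-survival impact of a patient navigation
    (integrated cancer care) program against a historic control cohort.
    Implements the full observational pipeline: patient-level table I/O and
    validation, a synthetic two-cohort generator with configurable
    confounding and right censoring, propensity-score estimation with
    standardized-mortality-ratio (ATT) weights, Rubin's B and R balance
    diagnostics, weighted Kaplan-Meier curves and log-rank tests, weighted
    Cox proportional-hazards models with robust (sandwich) variance and a
    Breslow baseline cumulative hazard, counterfactual g-computation of
    survival at fixed horizons with percentile-bootstrap uncertainty, and
    descriptive process/outcome tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
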