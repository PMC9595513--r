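#' Covariate dictionary for the patient-level study table
#'
#' One entry per modelled variable: its measurement kind, the admissible
#' category levels (ordered, first level = default reference), and its role
#' in the causal ordering of the study. Roles:
#' \describe{
#'   \item{id}{opaque identifier, never modelled.}
#'   \item{design}{the cohort (exposure) indicator.}
#'   \item{baseline}{measured before the first hospital cancer-suspect code
#'     (day 0); these enter the propensity-score model.}
#'   \item{process}{diagnostic process indicators completed between day 0
#'     and treatment initiation.}
#'   \item{treatment}{treatment modality indicators.}
#'   \item{intermediate}{intermediate outcomes at treatment initiation
#'     (stage, ECOG).}
#'   \item{outcome}{follow-up time and the death indicator.}
#' }
#'
#' "unknown" is a first-class category level (not missing data) wherever the
#' study tabulates it: hazard ratios are estimated for unknown onset, delay
#' class, stage and ECOG levels.
#'
#' @return named list of covariate specs; each spec is a list with elements
#'   `name`, `kind` ("continuous", "binary", "categorical"), `levels`,
#'   `reference`, `role`.
#' @export
covariate_dictionary <- function() {
  spec <- function(name, kind, role, levels = NULL, reference = NULL) {
    if (kind == "categorical") {
      if (is.null(reference)) reference <- levels[1L]
      stopifnot(reference %in% levels)
    }
    list(name = name, kind = kind, levels = levels,
         reference = reference, role = role)
  }
  specs <- list(
    spec("patient_id", "id", "id"),
    spec("cohort", "categorical", "design",
         levels = c("control", "intervention"), reference = "control"),
    spec("age", "continuous", "baseline"),
    spec("sex", "categorical", "baseline",
         levels = c("female", "male"), reference = "female"),
    spec("residence_type", "categorical", "baseline",
         levels = c("rural", "urban"), reference = "rural"),
    spec("residence_dev_score", "continuous", "baseline"),
    spec("onset_type", "categorical", "baseline",
         levels = c("asymptomatic", "symptomatic", "unknown"),
         reference = "asymptomatic"),
    spec("histology", "categorical", "baseline",
         levels = c("adenocarcinoma", "squamous", "neuroendocrine", "other_nos"),
         reference = "adenocarcinoma"),
    spec("onset_to_code_class", "categorical", "baseline",
         levels = c("q1", "q2", "q3", "q4", "unknown"), reference = "q1"),
    spec("prior_chest_ct", "binary", "baseline"),
    spec("prior_bronchoscopy", "binary", "baseline"),
    spec("prior_petct", "binary", "baseline"),
    spec("prior_scintigraphy", "binary", "baseline"),
    spec("prior_cytology", "binary", "baseline"),
    spec("prior_brain_imaging", "binary", "baseline"),
    spec("pre_tx_bronchoscopy", "binary", "process"),
    spec("pre_tx_petct", "binary", "process"),
    spec("pre_tx_brain_imaging", "binary", "process"),
    spec("pre_tx_cytology", "binary", "process"),
    spec("pre_tx_stage_documented", "binary", "process"),
    spec("pre_tx_tumor_board_recommendation", "binary", "process"),
    spec("resection_surgery", "binary", "treatment"),
    spec("chemotherapy", "binary", "treatment"),
    spec("radiotherapy", "binary", "treatment"),
    spec("stage_at_tx", "categorical", "intermediate",
         levels = c("I", "II", "III", "IV", "unknown"), reference = "I"),
    spec("ecog_at_tx", "categorical", "intermediate",
         levels = c("e0", "e1", "e2", "e3_4", "unknown"), reference = "e0"),
    spec("treatment_delay_days", "continuous", "process"),
    spec("followup_days", "continuous", "outcome"),
    spec("event", "binary", "outcome")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Baseline covariate names
#'
#' The covariates measured before day 0, i.e. the candidate confounders that
#' describe the two cohorts at study entry.
#' @return character vector of covariate names.
#' @export
baseline_covariates <- function() {
  d <- covariate_dictionary()
  names(d)[vapply(d, `[[`, character(1), "role") == "baseline"]
}

#' Default propensity-score model covariates
#'
#' All baseline covariates except prior scintigraphy (performed in too few
#' patients to support a coefficient) and except prior cytology only if it
#' turns out constant, which [fit_propensity()] detects and drops at fit time.
#' @return character vector of covariate names.
#' @export
ps_covariates <- function() {
  setdiff(baseline_covariates(), "prior_scintigraphy")
}

#' Post-baseline covariate names (process + treatment + intermediate)
#' @return character vector of covariate names.
#' @export
post_baseline_covariates <- function() {
  d <- covariate_dictionary()
  roles <- vapply(d, `[[`, character(1), "role")
  setdiff(names(d)[roles %in% c("process", "treatment", "intermediate")],
          "treatment_delay_days")
}
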