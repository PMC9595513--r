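# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: the partial likelihood is written out longhand
# and maximized by grid search; the product-limit values are hand products.

# Weighted Cox partial log-likelihood for a single covariate, no ties
# assumed (distinct event times): sum over deaths of
#   w_i * (x_i b - log sum_{j at risk} w_j exp(x_j b))
oracle_cox_loglik <- function(b, time, event, x, w) {
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- time >= time[i]
      ll <- ll + w[i] * (x[i] * b - log(sum(w[risk] * exp(x[risk] * b))))
    }
  }
  ll
}

oracle_cox_grid_mle <- function(time, event, x, w,
                                grid = seq(-4, 4, by = 1e-4)) {
  ll <- vapply(grid, oracle_cox_loglik, numeric(1),
               time = time, event = event, x = x, w = w)
  grid[which.max(ll)]
}

# Breslow baseline cumulative hazard by explicit risk-set sums
oracle_breslow <- function(time, event, x, w, b) {
  dt <- sort(unique(time[event == 1]))
  inc <- vapply(dt, function(t0) {
    sum(w[time == t0 & event == 1]) /
      sum(w[time >= t0] * exp(x[time >= t0] * b))
  }, numeric(1))
  data.frame(time = dt, cumhaz = cumsum(inc))
}

# A minimal valid record table built in code (no fixtures on disk)
make_records <- function(n = 8, cohort = rep(c("control", "intervention"),
                                             length.out = n),
                         followup = seq(40, by = 35, length.out = n),
                         event = rep(c(1, 0), length.out = n)) {
  dict <- covariate_dictionary()
  df <- data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    cohort = cohort,
    age = seq(55, 75, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    residence_type = rep(c("urban", "rural"), length.out = n),
    residence_dev_score = rep(c(40, 50), length.out = n),
    onset_type = rep(c("asymptomatic", "symptomatic"), length.out = n),
    histology = rep(c("adenocarcinoma", "squamous"), length.out = n),
    onset_to_code_class = rep(c("q1", "q2", "q3", "q4"), length.out = n),
    prior_chest_ct = rep(c(1, 0), length.out = n),
    prior_bronchoscopy = rep(0, n),
    prior_petct = rep(0, n),
    prior_scintigraphy = rep(0, n),
    prior_cytology = rep(0, n),
    prior_brain_imaging = rep(c(0, 1), length.out = n),
    pre_tx_bronchoscopy = rep(1, n),
    pre_tx_petct = rep(c(0, 1), length.out = n),
    pre_tx_brain_imaging = rep(c(1, 0), length.out = n),
    pre_tx_cytology = rep(1, n),
    pre_tx_stage_documented = rep(1, n),
    pre_tx_tumor_board_recommendation = rep(1, n),
    resection_surgery = rep(c(0, 1), length.out = n),
    chemotherapy = rep(c(1, 0), length.out = n),
    radiotherapy = rep(0, n),
    stage_at_tx = rep(c("I", "II", "III", "IV"), length.out = n),
    ecog_at_tx = rep(c("e0", "e1"), length.out = n),
    treatment_delay_days = rep(c(20, 60), length.out = n),
    followup_days = followup,
    event = event,
    stringsAsFactors = FALSE
  )
  validate_records(df, require_followup_30 = FALSE)
}

# Compact confounded generating world used across estimator tests:
# prior chest CT and age affect both cohort assignment and the hazard.
confounded_config <- function(n_total = 296, log_hr = log(0.63)) {
  synthetic_config(
    n_control = ceiling(n_total * 173 / 296),
    n_intervention = floor(n_total * 123 / 296),
    true_log_hr_intervention = log_hr,
    covariate_log_hrs = c(prior_chest_ct = log(1.4),
                          age_per_year = log(1.015)),
    assignment = "logistic",
    assignment_log_ors = c(prior_chest_ct = 1.1, age_per_year = 0.02),
    assignment_intercept = -0.85
  )
}

confounded_ps_covariates <- c("age", "prior_chest_ct")
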