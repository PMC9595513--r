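test_that("weighted KM: hand product-limit, censoring, weight-frequency
           equivalence", {
  # all censored: S identically 1 (no event times on the curve)
  km <- weighted_km(c(10, 20, 30), c(0, 0, 0))
  expect_identical(nrow(km), 0L)
  expect_equal(km_survival_at(km, c(0, 50)), c(1, 1))

  # unit weights, hand product-limit: S(1)=2/3, S(2)=1/3, S(3)=1/3
  km <- weighted_km(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$time, c(1, 2))
  expect_equal(km$survival, c(2 / 3, 1 / 3))
  expect_equal(km_survival_at(km, 1:3), c(2 / 3, 1 / 3, 1 / 3))
  expect_equal(km$at_risk_weighted, c(3, 2))

  # duplicating a patient vs doubling its weight: identical curves
  t0 <- c(5, 9, 9, 14, 20); e0 <- c(1, 1, 0, 1, 0)
  dup <- weighted_km(c(t0, 9), c(e0, 1))
  dbl <- weighted_km(t0, e0, weights = c(1, 2, 1, 1, 1))
  expect_equal(data.frame(dup), data.frame(dbl))

  # unit weights equal the classical product-limit estimator
  set.seed(8)
  tt <- sample(1:50, 40, replace = TRUE); ee <- rbinom(40, 1, 0.6)
  km <- weighted_km(tt, ee)
  sf <- survival::survfit(survival::Surv(tt, ee) ~ 1)
  expect_equal(km_survival_at(km, sort(unique(tt))),
               summary(sf, times = sort(unique(tt)))$surv, tolerance = 1e-12)

  expect_error(weighted_km(1:3, c(1, 1, 0), weights = c(1, -1, 1)),
               class = "navsurv_domain_error")
})

test_that("weighted log-rank: mirrored data, classical equivalence, and the
           robust variant", {
  # identical survival experience in both groups
  tt <- rep(c(3, 8, 15, 30), 2); ee <- rep(c(1, 0, 1, 1), 2)
  gg <- rep(c("a", "b"), each = 4)
  lr <- weighted_logrank(tt, ee, group = gg, variant = "naive")
  expect_lt(lr$chi2, 1e-10)
  expect_equal(lr$p, 1, tolerance = 1e-6)

  # unit weights: naive variant equals the classical log-rank (survdiff)
  set.seed(14)
  tt <- sample(1:80, 60, replace = TRUE); ee <- rbinom(60, 1, 0.7)
  gg <- rep(c("a", "b"), 30)
  lr <- weighted_logrank(tt, ee, group = gg, variant = "naive")
  sd <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
  expect_equal(lr$chi2, sd$chisq, tolerance = 1e-10)

  # robust variant agrees with the robust score test of the weighted Cox fit
  w <- runif(60, 0.5, 2)
  lr_r <- weighted_logrank(tt, ee, w, gg)
  cf <- survival::coxph(survival::Surv(tt, ee) ~ gg, weights = w, robust = TRUE)
  expect_equal(lr_r$chi2, as.numeric(cf$rscore), tolerance = 1e-12)

  expect_error(weighted_logrank(tt, ee, group = rep("a", 60)),
               class = "navsurv_domain_error")
})

test_that("weighted Cox matches the brute-force partial-likelihood oracle and
           the null; robust CIs are exp(log_hr +/- 1.96 se)", {
  # n = 4 toy, unit weights, distinct times
  tt <- c(2, 5, 8, 11); ee <- c(1, 1, 0, 1); x <- c(1, 0, 1, 0)
  rec <- make_records(4, followup = tt, event = ee)
  rec$prior_chest_ct <- x
  fit <- fit_weighted_cox(rec, terms = "prior_chest_ct")
  expect_equal(unname(fit$log_hr), oracle_cox_grid_mle(tt, ee, x, rep(1, 4)),
               tolerance = 1e-3)

  # non-unit weights against the same oracle
  w <- c(2, 0.5, 1, 1.5)
  fit_w <- fit_weighted_cox(rec, weights = w, terms = "prior_chest_ct")
  expect_equal(unname(fit_w$log_hr), oracle_cox_grid_mle(tt, ee, x, w),
               tolerance = 1e-3)

  expect_equal(fit$ci_lower, exp(fit$log_hr - 1.96 * fit$se), tolerance = 1e-12)
  expect_equal(fit$ci_upper, exp(fit$log_hr + 1.96 * fit$se), tolerance = 1e-12)

  # covariate independent of survival: HR near 1 at large n
  set.seed(5)
  big <- generate_cohort(synthetic_config(n_control = 1500, n_intervention = 1500,
                                          true_log_hr_intervention = 0,
                                          covariate_log_hrs = c(prior_chest_ct = 0)),
                         seed = 6, raw = TRUE)
  big$noise <- rbinom(nrow(big), 1, 0.5)
  fitn <- fit_weighted_cox(big, terms = "noise")
  expect_lt(abs(fitn$log_hr), 0.12)

  expect_error(fit_weighted_cox(make_records(4, event = rep(0, 4))),
               class = "navsurv_fit_error")
})

test_that("weight-frequency equivalence: integer weights reproduce the
           replicated-data point estimates exactly", {
  rec <- generate_cohort(synthetic_config(n_control = 60, n_intervention = 50),
                         seed = 12)
  set.seed(1)
  w <- sample(1:3, nrow(rec), replace = TRUE)
  rep_idx <- rep(seq_len(nrow(rec)), w)
  # Breslow ties: the partial likelihood with integer case weights is then
  # exactly the replicated-data likelihood (Efron's weighted tie correction
  # is intentionally not frequency-consistent)
  fit_w <- fit_weighted_cox(rec, w, terms = c("cohort", "age"), ties = "breslow")
  fit_r <- fit_weighted_cox(rec[rep_idx, ], terms = c("cohort", "age"),
                            ties = "breslow")
  expect_equal(fit_w$log_hr, fit_r$log_hr, tolerance = 1e-10)
  expect_equal(fit_w$baseline_cumhaz, fit_r$baseline_cumhaz, tolerance = 1e-10)
  km_w <- weighted_km(rec$followup_days, rec$event, w)
  km_r <- weighted_km(rec$followup_days[rep_idx], rec$event[rep_idx])
  expect_equal(data.frame(km_w), data.frame(km_r), tolerance = 1e-12)
})

test_that("model specifications carry the study's term sets and references", {
  sp <- model_specifications()
  expect_identical(sp$univariate, "cohort")
  expect_true(all(c("onset_type", "histology", "prior_chest_ct",
                    "onset_to_code_class") %in% sp$baseline))
  expect_true(all(c("stage_at_tx", "ecog_at_tx", "resection_surgery",
                    "chemotherapy", "radiotherapy",
                    "pre_tx_tumor_board_recommendation") %in% sp$post_baseline))
  expect_false("prior_chest_ct" %in% sp$post_baseline)
  d <- covariate_dictionary()
  expect_identical(d$onset_type$reference, "asymptomatic")
  expect_identical(d$stage_at_tx$reference, "I")
  expect_identical(d$ecog_at_tx$reference, "e0")
  expect_identical(d$histology$reference, "adenocarcinoma")
  expect_identical(d$onset_to_code_class$reference, "q1")
})

test_that("predict_survival: t = 0, reference identity, Breslow oracle,
           extrapolation warning", {
  tt <- c(3, 6, 9, 12, 20); ee <- c(1, 1, 1, 0, 1); x <- c(1, 0, 0, 1, 1)
  rec <- make_records(5, followup = tt, event = ee)
  rec$prior_chest_ct <- x
  fit <- fit_weighted_cox(rec, terms = "prior_chest_ct", ties = "breslow")
  ref <- data.frame(prior_chest_ct = 0)
  expect_equal(predict_survival(fit, ref, 0), 1)
  # reference pattern: S = exp(-H0) by construction
  expect_equal(predict_survival(fit, ref, c(3, 6, 9)),
               exp(-fit$baseline_cumhaz$cumhaz[1:3]), tolerance = 1e-12)
  # hand-composed Breslow risk-set sums at the fitted coefficient
  orc <- oracle_breslow(tt, ee, x, rep(1, 5), unname(fit$log_hr))
  expect_equal(fit$baseline_cumhaz$cumhaz, orc$cumhaz, tolerance = 1e-10)
  # non-reference pattern composes through exp(x beta)
  expect_equal(predict_survival(fit, data.frame(prior_chest_ct = 1), 9),
               exp(-orc$cumhaz[3] * exp(unname(fit$log_hr))), tolerance = 1e-10)
  expect_warning(predict_survival(fit, ref, 50), "extrapolat")
  expect_error(predict_survival(fit, ref, -1), class = "navsurv_domain_error")
})
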