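test_that("identical cohorts give constant PS; 2x2 logistic matches the
           closed-form log odds", {
  # duplicated records: covariates carry no information about cohort
  rec <- rbind(make_records(6, cohort = rep("control", 6)),
               make_records(6, cohort = rep("intervention", 6)))
  prop <- fit_propensity(rec, covariates = c("sex", "prior_chest_ct"))
  expect_equal(unname(prop$ps), rep(0.5, 12), tolerance = 1e-6)

  # single binary covariate with known 2x2 counts:
  # control:      x=0 30, x=1 10 ; intervention: x=0 10, x=1 20
  n <- c(30, 10, 10, 20)
  x <- rep(c(0, 1, 0, 1), n)
  coh <- rep(c("control", "control", "intervention", "intervention"), n)
  rec <- make_records(70, cohort = coh)
  rec$prior_chest_ct <- x
  prop <- fit_propensity(rec, covariates = "prior_chest_ct")
  expect_equal(unname(prop$coefficients["(Intercept)"]), log(10 / 30),
               tolerance = 1e-6)
  expect_equal(unname(prop$coefficients["prior_chest_ct"]),
               log((20 / 10) / (10 / 30)), tolerance = 1e-6)
})

test_that("zero-variance covariates are dropped and recorded, not fatal", {
  rec <- generate_cohort(synthetic_config(n_control = 100, n_intervention = 80),
                         seed = 21)
  expect_true(all(rec$prior_cytology == 0))  # 0% in both cohorts by design
  prop <- fit_propensity(rec)
  expect_true("prior_cytology" %in% prop$dropped_terms)
  expect_false("prior_cytology" %in% prop$terms)
  expect_length(prop$coefficients, length(prop$terms))
  expect_true(all(prop$ps > 0 & prop$ps < 1))
  expect_false("prior_scintigraphy" %in% c(prop$terms, prop$dropped_terms))
})

test_that("perfect separation raises an explicit error naming a term", {
  rec <- make_records(20, cohort = rep(c("control", "intervention"), each = 10))
  rec$prior_chest_ct <- as.integer(rec$cohort == "intervention")
  err <- expect_error(fit_propensity(rec, covariates = "prior_chest_ct"),
                      class = "navsurv_separation_error")
  expect_match(conditionMessage(err), "prior_chest_ct")
  expect_error(fit_propensity(make_records(3, cohort = c("control", "control",
                                                          "intervention"))),
               class = "navsurv_fit_error")
})

test_that("SMR weights follow the ATT formula and reject bad scores", {
  expect_identical(compute_smr_weights(0.73, "intervention"), 1)
  expect_equal(compute_smr_weights(0.5, "control"), 1)
  expect_equal(compute_smr_weights(0.8, "control"), 4)
  expect_error(compute_smr_weights(c(0, 0.4), c("control", "control")),
               class = "navsurv_domain_error")
  expect_error(compute_smr_weights(1, "intervention"),
               class = "navsurv_domain_error")
  expect_warning(
    compute_smr_weights(c(rep(0.1, 50), 0.999), rep("control", 51)),
    "extreme")
  # sum of control weights is finite and positive
  rec <- generate_cohort(synthetic_config(n_control = 80, n_intervention = 60),
                         seed = 4)
  prop <- fit_propensity(rec)
  w <- compute_smr_weights(prop$ps, rec$cohort)
  expect_true(all(w[rec$cohort == "intervention"] == 1))
  sw <- sum(w[rec$cohort == "control"])
  expect_true(is.finite(sw) && sw > 0)
})

test_that("Rubin's B and R match hand arithmetic and their invariances", {
  ps <- c(0.6, 0.8, 0.4, 0.6)
  coh <- c("intervention", "intervention", "control", "control")
  # hand: means .7/.5, population variances .01/.01
  expect_equal(rubins_b(ps, coh), 100 * 0.2 / sqrt(0.01), tolerance = 1e-12)
  expect_equal(rubins_r(ps, coh), 1, tolerance = 1e-12)
  # identical distributions: B = 0, R = 1
  ps2 <- c(0.3, 0.5, 0.3, 0.5)
  expect_equal(rubins_b(ps2, coh), 0)
  expect_equal(rubins_r(ps2, coh), 1)
  # control variance 4x intervention: R = 1/4
  ps3 <- c(0.5, 0.6, 0.4, 0.6)
  expect_equal(rubins_r(ps3, coh), 0.25)
  # invariant to patient relabeling and uniform within-cohort weight rescaling
  set.seed(42)
  ps4 <- runif(40, 0.2, 0.8)
  coh4 <- rep(c("control", "intervention"), 20)
  w4 <- runif(40, 0.5, 2)
  perm <- sample(40)
  expect_equal(rubins_b(ps4, coh4, w4), rubins_b(ps4[perm], coh4[perm], w4[perm]))
  w5 <- w4 * ifelse(coh4 == "control", 7, 0.3)
  expect_equal(rubins_b(ps4, coh4, w4), rubins_b(ps4, coh4, w5))
  expect_equal(rubins_r(ps4, coh4, w4), rubins_r(ps4, coh4, w5))
  # degenerate variance errors
  expect_error(rubins_b(c(0.5, 0.5, 0.5, 0.5), coh),
               class = "navsurv_domain_error")
  expect_error(rubins_r(c(0.4, 0.6, 0.5, 0.5), coh),
               class = "navsurv_domain_error")
  # logit-scale option differs from the PS scale on asymmetric data
  expect_false(isTRUE(all.equal(rubins_b(ps4, coh4, scale = "logit"),
                                rubins_b(ps4, coh4))))
})

test_that("balance table: unit weights collapse to unweighted; true-PS SMR
           weighting balances a confounded covariate; B improves", {
  rec <- generate_cohort(confounded_config(3000), seed = 31, raw = TRUE)
  prop <- fit_propensity(rec, covariates = confounded_ps_covariates)
  w <- compute_smr_weights(prop$ps, rec$cohort)

  bal <- balance_table(rec, rep(1, nrow(rec)), prop$ps,
                       covariates = c("age", "prior_chest_ct"))
  expect_equal(bal$control_unweighted, bal$control_weighted, tolerance = 1e-12)

  bal_w <- balance_table(rec, w, prop$ps,
                         covariates = c("age", "prior_chest_ct"))
  ct <- bal_w[bal_w$variable == "prior_chest_ct", ]
  # weighted control proportion moves to the intervention side
  expect_lt(abs(ct$control_weighted - ct$intervention), 3)
  expect_gt(abs(ct$control_unweighted - ct$intervention), 8)
  rb <- attr(bal_w, "rubins")
  expect_lt(rb$b_weighted, rb$b_unweighted)
  expect_true(rb$pass_b)
  expect_gt(rb$r_weighted, 0)
  expect_identical(rb$pass_r, rb$r_weighted >= 0.5 && rb$r_weighted <= 2)
})
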