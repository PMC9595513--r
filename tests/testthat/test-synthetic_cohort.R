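test_that("generator hits the configured sizes, is seed-deterministic, and
           eligible output satisfies the record invariants", {
  cfg <- synthetic_config(n_control = 173, n_intervention = 123)
  a <- generate_cohort(cfg, seed = 9)
  b <- generate_cohort(cfg, seed = 9)
  c2 <- generate_cohort(cfg, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, c2))
  expect_identical(as.integer(table(a$cohort)), c(173L, 123L))
  expect_true(all(a$followup_days >= 30))
  expect_true(all(a$event %in% 0:1))
  expect_s3_class(validate_records(a), "data.frame")
  # exclusion log accounts for every raw draw
  expect_true(all(unlist(attr(a, "exclusion_log")) >= 0))
})

test_that("configured covariate prevalences are reproduced at scale", {
  cfg <- synthetic_config(n_control = 5000, n_intervention = 5000)
  r <- generate_cohort(cfg, seed = 123, raw = TRUE)
  ctl <- r$cohort == "control"
  # 99% binomial interval around the configured control chest-CT prevalence
  p0 <- 0.688
  phat <- mean(r$prior_chest_ct[ctl])
  half <- qnorm(0.995) * sqrt(p0 * (1 - p0) / sum(ctl))
  expect_gt(phat, p0 - half)
  expect_lt(phat, p0 + half)
  # intervention-side imbalance present by construction
  expect_lt(mean(r$prior_chest_ct[!ctl]), phat)
  expect_gt(mean(r$prior_bronchoscopy[!ctl]), mean(r$prior_bronchoscopy[ctl]))
})

test_that("invalid configs are rejected", {
  expect_error(synthetic_config(n_control = 0), class = "navsurv_config_error")
  expect_error(synthetic_config(baseline_hazard = c(shape = -1, scale = 900)),
               class = "navsurv_config_error")
  expect_error(synthetic_config(censoring = c(horizon = 10, dropout_rate = 0)),
               class = "navsurv_config_error")
  cm <- default_covariate_model(); cm$control$prior_chest_ct <- 1.2
  expect_error(synthetic_config(covariate_model = cm),
               class = "navsurv_config_error")
  expect_error(generate_cohort(synthetic_config()),
               class = "navsurv_config_error")  # no seed anywhere
})

test_that("eligibility filter applies the stated boundary conventions and
           first-match exclusion counting", {
  base <- as.data.frame(make_records(6, followup = c(400, 20, 400, 400, 25, 31),
                                     event = c(1, 1, 1, 1, 0, 1)))
  base$tumor_board_day <- c(15, 10, 2, 3, 12, 4)
  base$treatment_start_day <- c(40, 30, 5, 6, NA, 8)
  # row 1: retained; row 2: death day 20 (<30 rule); row 3 and 4: board <= 3
  # (even though treatment is also <= 7, counted once under the board rule);
  # row 5: lost before day 30; row 6: day-31 death with board day 4 retained
  flt <- apply_eligibility_filters(base)
  expect_identical(flt$exclusion_log,
                   list(short_delay_tumor_board = 2L,
                        short_delay_treatment = 0L,
                        death_before_day30 = 1L,
                        lost_before_day30 = 1L,
                        retained = 2L))
  expect_identical(flt$eligible$patient_id, c("T001", "T006"))

  # treatment within 7 days alone
  one <- base[1, , drop = FALSE]
  one$treatment_start_day <- 7
  expect_identical(apply_eligibility_filters(one)$exclusion_log$short_delay_treatment, 1L)
  # day-30 death is retained ("< 30 days survival" is strict)
  one <- base[1, , drop = FALSE]
  one$followup_days <- 30; one$event <- 1
  expect_identical(apply_eligibility_filters(one)$exclusion_log$retained, 1L)
  # empty input yields empty output
  empty <- apply_eligibility_filters(base[0, , drop = FALSE])
  expect_identical(nrow(empty$eligible), 0L)
})

test_that("raw generation returns exact unfiltered counts with auxiliaries", {
  r <- generate_cohort(synthetic_config(n_control = 50, n_intervention = 40),
                       seed = 3, raw = TRUE)
  expect_identical(nrow(r), 90L)
  expect_true(all(c("tumor_board_day", "treatment_start_day",
                    "lost_to_followup_day") %in% names(r)))
  # untreated patients have no treatment delay
  untreated <- r$resection_surgery + r$chemotherapy + r$radiotherapy == 0
  expect_true(all(is.na(r$treatment_delay_days[untreated])))
  expect_true(all(!is.na(r$treatment_delay_days[!untreated])))
})

test_that("logistic assignment induces confounding visible in the raw data", {
  r <- generate_cohort(confounded_config(4000), seed = 77, raw = TRUE)
  expect_gt(mean(r$prior_chest_ct[r$cohort == "intervention"]),
            mean(r$prior_chest_ct[r$cohort == "control"]) + 0.05)
  # both cohorts well populated
  expect_true(all(table(r$cohort) > 1000))
})
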