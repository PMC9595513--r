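test_that("validation is total: enums, binaries, ranges, inclusion floor", {
  rec <- make_records(8)
  expect_s3_class(rec$cohort, "factor")
  expect_setequal(levels(rec$onset_type), c("asymptomatic", "symptomatic", "unknown"))

  bad <- as.data.frame(rec); bad$stage_at_tx <- as.character(bad$stage_at_tx)
  bad$stage_at_tx[3] <- "V"
  err <- expect_error(validate_records(bad), class = "navsurv_validation_error")
  expect_match(conditionMessage(err), "stage_at_tx")
  expect_match(conditionMessage(err), "row 3")

  bad <- as.data.frame(rec); bad$event[2] <- 2
  expect_error(validate_records(bad), class = "navsurv_validation_error")

  bad <- as.data.frame(rec); bad$residence_dev_score[1] <- 101
  expect_error(validate_records(bad), class = "navsurv_validation_error")

  bad <- as.data.frame(rec); bad$followup_days[5] <- 29
  expect_error(validate_records(bad), class = "navsurv_validation_error")
  expect_silent(validate_records(bad, require_followup_30 = FALSE))

  # category strings normalize case-insensitively
  up <- as.data.frame(rec)
  up$cohort <- toupper(as.character(up$cohort))
  up$histology <- toupper(as.character(up$histology))
  norm <- validate_records(up)
  expect_identical(as.character(norm$cohort), as.character(rec$cohort))
})

test_that("missing required column raises a schema error naming it", {
  rec <- as.data.frame(make_records(4))
  rec$prior_petct <- NULL
  err <- expect_error(validate_records(rec), class = "navsurv_schema_error")
  expect_match(conditionMessage(err), "prior_petct")
})

test_that("write/read round-trip is the identity on valid record lists", {
  rec <- generate_cohort(synthetic_config(n_control = 20, n_intervention = 15),
                         seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_table(rec, path)
  back <- suppressMessages(read_study_table(path))
  for (nm in names(covariate_dictionary())) {
    if (is.factor(rec[[nm]])) {
      expect_identical(as.character(back[[nm]]), as.character(rec[[nm]]),
                       label = nm)
    } else {
      expect_equal(back[[nm]], rec[[nm]], label = nm, tolerance = 0)
    }
  }
  # load report counts rows per cohort
  expect_identical(attr(back, "load_report"),
                   list(control = 20L, intervention = 15L))
})

test_that("missing treatment delay survives the round trip as NA, not 0", {
  rec <- make_records(4)
  rec$treatment_delay_days[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_table(rec, path)
  fields_row2 <- strsplit(readLines(path)[3], ",")[[1]]
  delay_col <- match("treatment_delay_days", names(covariate_dictionary()))
  expect_identical(fields_row2[delay_col], "")
  back <- suppressMessages(read_study_table(path))
  expect_true(is.na(back$treatment_delay_days[2]))
  expect_false(is.na(back$treatment_delay_days[1]))
})

test_that("degenerate inputs: header-only file, zero records, column map", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(names(covariate_dictionary()), collapse = ","), path)
  expect_error(suppressMessages(read_study_table(path)),
               class = "navsurv_empty_error")

  rec <- make_records(3)
  out <- withr::local_tempfile(fileext = ".csv")
  write_study_table(rec[0, ], out)
  expect_length(readLines(out), 1L)
  write_study_table(rec, out)
  expect_length(readLines(out), 4L)

  # renamed source headers come back through a column map
  renamed <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(rec)
  names(df)[names(df) == "cohort"] <- "study arm (0 pre / 1 post)"
  utils::write.csv(df, renamed, row.names = FALSE)
  back <- suppressMessages(read_study_table(
    renamed, column_map = c(cohort = "study arm (0 pre / 1 post)")))
  expect_identical(as.character(back$cohort), as.character(rec$cohort))
  expect_error(
    suppressMessages(read_study_table(renamed, column_map = c(cohort = "nope"))),
    class = "navsurv_schema_error")
})
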