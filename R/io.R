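#' Validate a patient-level study table
#'
#' Checks every field of every record against the covariate dictionary:
#' category values (normalized case-insensitively), binary indicators in
#' \{0, 1\}, development score in \[0, 100\], nonnegative follow-up of at
#' least 30 days (the eligibility floor), and `event` in \{0, 1\}.
#' Validation is total: no invalid record can enter downstream modules.
#'
#' @param records data frame of patient records with canonical column names.
#' @param require_followup_30 enforce the `followup_days >= 30` inclusion
#'   invariant (default TRUE; raw pre-eligibility data may turn it off).
#' @return the validated data frame with categorical columns as factors in
#'   dictionary level order.
#' @export
validate_records <- function(records, require_followup_30 = TRUE) {
  dict <- covariate_dictionary()
  required <- names(dict)
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L)
    ns_stop("navsurv_schema_error",
            "missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0L)
    ns_stop("navsurv_empty_error", "study table contains no patient rows")

  for (nm in required) {
    sp <- dict[[nm]]
    x <- records[[nm]]
    if (sp$kind == "categorical") {
      xs <- tolower(trimws(as.character(x)))
      lv <- sp$levels
      idx <- match(xs, tolower(lv))
      if (anyNA(idx)) {
        bad <- which(is.na(idx))[1L]
        ns_stop("navsurv_validation_error",
                "invalid value '", as.character(x)[bad], "' for field '", nm,
                "' in row ", bad, " (allowed: ", paste(lv, collapse = ", "), ")")
      }
      records[[nm]] <- factor(lv[idx], levels = lv)
    } else if (sp$kind == "binary") {
      xv <- suppressWarnings(as.numeric(x))
      bad <- which(!(xv %in% c(0, 1)))
      if (length(bad) > 0L)
        ns_stop("navsurv_validation_error",
                "field '", nm, "' must be 0/1; row ", bad[1L],
                " has '", as.character(x)[bad[1L]], "'")
      records[[nm]] <- as.integer(xv)
    } else if (sp$kind == "continuous") {
      xv <- suppressWarnings(as.numeric(x))
      introduced <- which(is.na(xv) & !is.na(x) & trimws(as.character(x)) != "")
      if (length(introduced) > 0L)
        ns_stop("navsurv_validation_error",
                "field '", nm, "' must be numeric; row ", introduced[1L],
                " has '", as.character(x)[introduced[1L]], "'")
      records[[nm]] <- xv
    } else {
      records[[nm]] <- as.character(x)
    }
  }

  bad <- which(is.na(records$followup_days) | records$followup_days < 0)
  if (length(bad) > 0L)
    ns_stop("navsurv_validation_error",
            "followup_days missing or negative in row ", bad[1L])
  if (require_followup_30) {
    bad <- which(records$followup_days < 30)
    if (length(bad) > 0L)
      ns_stop("navsurv_validation_error",
              "followup_days < 30 in row ", bad[1L],
              " violates the 30-day inclusion criterion")
  }
  bad <- which(!is.na(records$residence_dev_score) &
               (records$residence_dev_score < 0 | records$residence_dev_score > 100))
  if (length(bad) > 0L)
    ns_stop("navsurv_validation_error",
            "residence_dev_score outside [0, 100] in row ", bad[1L])
  bad <- which(!is.na(records$treatment_delay_days) & records$treatment_delay_days < 0)
  if (length(bad) > 0L)
    ns_stop("navsurv_validation_error",
            "treatment_delay_days negative in row ", bad[1L])
  records
}

#' Read a patient-level study table
#'
#' Reads the canonical CSV interchange format (UTF-8, comma separated, "."
#' decimal) or, when `dialect = "spreadsheet"`, the first sheet of an xlsx
#' file via readxl. A column-name map translates the source file's headers
#' (which may carry explanatory comments) to the canonical names of
#' [covariate_dictionary()]; columns not in the dictionary are passed
#' through unvalidated.
#'
#' Missing `treatment_delay_days` (untreated patients) is encoded as an
#' empty field, never 0: a zero-day delay is legal data.
#'
#' @param path file path.
#' @param dialect "csv" (default) or "spreadsheet".
#' @param column_map named character vector `canonical = source_header`, or
#'   the path of a JSON file holding one; NULL if headers are already
#'   canonical.
#' @param require_followup_30 see [validate_records()].
#' @return validated data frame of patient records; attribute `load_report`
#'   holds the per-cohort row counts.
#' @export
read_study_table <- function(path, dialect = c("csv", "spreadsheet"),
                             column_map = NULL, require_followup_30 = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    ns_stop("navsurv_io_error", "file not found: ", path)
  df <- if (dialect == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("", "NA"))
  } else {
    if (!requireNamespace("readxl", quietly = TRUE))
      ns_stop("navsurv_io_error",
              "the spreadsheet dialect needs the 'readxl' package")
    as.data.frame(readxl::read_excel(path), check.names = FALSE)
  }
  if (is.character(column_map) && length(column_map) == 1L && is.null(names(column_map)) &&
      file.exists(column_map))
    column_map <- unlist(jsonlite::read_json(column_map, simplifyVector = TRUE))
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (!src %in% names(df))
        ns_stop("navsurv_schema_error",
                "column-map source column not found: ", src)
      names(df)[names(df) == src] <- canonical
    }
  }
  df <- validate_records(df, require_followup_30 = require_followup_30)
  report <- table(df$cohort)
  attr(df, "load_report") <- as.list(report)
  message("read_study_table: ", nrow(df), " records (",
          paste(sprintf("%s = %d", names(report), as.integer(report)),
                collapse = ", "), ")")
  df
}

#' Write a patient-level study table as canonical CSV
#'
#' Inverse of [read_study_table()]: categorical fields are written as their
#' level labels, binaries as 0/1, continuous fields at full precision, and
#' missing values as empty fields. Round-trips bit-exactly for categorical
#' and integer fields.
#'
#' @param records validated data frame of patient records.
#' @param path output file path.
#' @export
write_study_table <- function(records, path) {
  if (nrow(records) > 0L)
    records <- validate_records(records, require_followup_30 = FALSE)
  canonical <- intersect(names(covariate_dictionary()), names(records))
  extra <- setdiff(names(records), canonical)
  out <- records[, c(canonical, extra), drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    ns_stop("navsurv_io_error", "cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}
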