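# Design-based two-sample tests on weighted data. Weights are treated as
# probability weights: weighted point estimates with Kish effective sample
# sizes in the variance, so unit weights reduce to the classical tests.

weighted_t_test <- function(x_int, x_ctl, w_ctl = NULL) {
  if (is.null(w_ctl)) w_ctl <- rep(1, length(x_ctl))
  m1 <- mean(x_int); v1 <- stats::var(x_int); n1 <- length(x_int)
  m2 <- weighted_mean(x_ctl, w_ctl)
  n2 <- effective_n(w_ctl)
  # n/(n-1)-corrected weighted variance so unit weights equal var()
  v2 <- weighted_var(x_ctl, w_ctl) * n2 / max(n2 - 1, 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  tval <- (m1 - m2) / se
  df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / max(n2 - 1, 1))
  2 * stats::pt(-abs(tval), df)
}

weighted_chisq_test <- function(x, cohort, weights) {
  # weighted contingency table rescaled to the effective sample size
  int <- cohort == "intervention"
  lev <- if (is.factor(x)) levels(droplevels(x)) else sort(unique(x))
  tab <- rbind(
    vapply(lev, function(l) sum(weights[!int][x[!int] == l]), numeric(1)),
    vapply(lev, function(l) sum(weights[int][x[int] == l]), numeric(1))
  )
  n_eff <- c(effective_n(weights[!int]), effective_n(weights[int]))
  tab <- tab / rowSums(tab) * n_eff
  if (any(colSums(tab) == 0) || ncol(tab) < 2L) return(NA_real_)
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}

#' Covariate balance table with Rubin's B/R diagnostics
#'
#' The study-entry comparison table: for every baseline covariate, the
#' unweighted control summary, the SMR-weighted control summary, and the
#' intervention summary (whose weights are all 1, so weighted and
#' unweighted intervention data are identical), with comparison p-values
#' against the intervention cohort (chi-squared for categorical, two-sample
#' t for continuous; design-based variants on the weighted side). Rubin's B
#' and R before and after weighting are appended with pass flags against
#' the B < 25 and 0.5 <= R <= 2 thresholds.
#'
#' @param records validated patient records.
#' @param weights SMR weights from [compute_smr_weights()].
#' @param ps fitted propensity scores (for the B/R rows).
#' @param covariates covariates to tabulate (default all baseline).
#' @param scale scale for B/R, see [rubins_b()].
#' @return object of class `balance_report`: a data frame of rows
#'   (variable, level, type, control_unweighted, control_weighted,
#'   intervention, p_unweighted, p_weighted) with attributes `rubins` (the
#'   four diagnostics + pass flags).
#' @export
balance_table <- function(records, weights, ps,
                          covariates = baseline_covariates(),
                          scale = c("ps", "logit")) {
  scale <- match.arg(scale)
  int <- records$cohort == "intervention"
  w1 <- rep(1, nrow(records))
  rows <- list()
  for (nm in covariates) {
    x <- records[[nm]]
    sp <- covariate_dictionary()[[nm]]
    if (sp$kind == "continuous") {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, level = "mean",
        type = "continuous",
        control_unweighted = weighted_mean(x[!int]),
        control_weighted = weighted_mean(x[!int], weights[!int]),
        intervention = weighted_mean(x[int]),
        p_unweighted = weighted_t_test(x[int], x[!int]),
        p_weighted = weighted_t_test(x[int], x[!int], weights[!int])
      )
    } else {
      xf <- if (sp$kind == "binary") factor(x, levels = c(0, 1)) else x
      lev <- if (sp$kind == "binary") "1" else sp$levels
      p_u <- weighted_chisq_test(xf, records$cohort, w1)
      p_w <- weighted_chisq_test(xf, records$cohort, weights)
      for (l in lev) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = nm, level = l, type = sp$kind,
          control_unweighted = 100 * weighted_mean(as.numeric(xf[!int] == l)),
          control_weighted = 100 * weighted_mean(as.numeric(xf[!int] == l),
                                                 weights[!int]),
          intervention = 100 * weighted_mean(as.numeric(xf[int] == l)),
          p_unweighted = p_u, p_weighted = p_w
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rubins <- list(
    b_unweighted = rubins_b(ps, records$cohort, scale = scale),
    b_weighted = rubins_b(ps, records$cohort, weights, scale = scale),
    r_unweighted = rubins_r(ps, records$cohort, scale = scale),
    r_weighted = rubins_r(ps, records$cohort, weights, scale = scale)
  )
  rubins$pass_b <- rubins$b_weighted < 25
  rubins$pass_r <- rubins$r_weighted >= 0.5 && rubins$r_weighted <= 2
  structure(out, rubins = rubins, class = c("balance_report", "data.frame"))
}

#' @export
print.balance_report <- function(x, digits = 1, ...) {
  cat("Baseline covariate balance (control unweighted / weighted vs intervention)\n")
  df <- as.data.frame(x)
  df$control_unweighted <- round(df$control_unweighted, digits)
  df$control_weighted <- round(df$control_weighted, digits)
  df$intervention <- round(df$intervention, digits)
  df$p_unweighted <- signif(df$p_unweighted, 2)
  df$p_weighted <- signif(df$p_weighted, 2)
  print.data.frame(df, row.names = FALSE)
  r <- attr(x, "rubins")
  cat(sprintf("Rubin's B: %.3f (unweighted) -> %.3f (weighted) [pass: %s]\n",
              r$b_unweighted, r$b_weighted, r$pass_b))
  cat(sprintf("Rubin's R: %.3f (unweighted) -> %.3f (weighted) [pass: %s]\n",
              r$r_unweighted, r$r_weighted, r$pass_r))
  invisible(x)
}
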