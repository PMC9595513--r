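#' Fit the propensity-score model
#'
#' Maximum-likelihood logistic regression of cohort membership
#' (intervention vs control) on baseline covariates. Zero-variance
#' covariates (constant in the data, e.g. an investigation performed in 0\%
#' of both cohorts) and factor levels unobserved in the data are dropped
#' before/at fitting and recorded in `dropped_terms` rather than treated as
#' fatal. Perfect separation and non-convergence raise explicit errors.
#'
#' @param records validated patient records.
#' @param covariates names of the model covariates (default:
#'   [ps_covariates()], i.e. all baseline covariates except prior
#'   scintigraphy).
#' @return object of class `propensity_result`: `terms`, `coefficients`,
#'   `ps` (strictly inside (0,1)), `dropped_terms`, `converged`, and the
#'   underlying `glm` fit.
#' @export
fit_propensity <- function(records, covariates = ps_covariates()) {
  if (!all(covariates %in% names(records)))
    ns_stop("navsurv_schema_error", "missing covariate column(s): ",
            paste(setdiff(covariates, names(records)), collapse = ", "))
  tab <- table(records$cohort)
  if (length(tab) < 2L || any(tab < 2L))
    ns_stop("navsurv_fit_error", "need at least 2 records per cohort")

  dat <- records[, covariates, drop = FALSE]
  dropped <- character(0)
  for (nm in covariates) {
    x <- dat[[nm]]
    if (is.factor(x)) x <- droplevels(x)
    constant <- if (is.factor(x)) nlevels(x) < 2L else
      (stats::var(as.numeric(x)) == 0 || all(is.na(x)))
    if (constant) {
      dropped <- c(dropped, nm)
      dat[[nm]] <- NULL
    } else if (is.factor(dat[[nm]])) {
      dat[[nm]] <- droplevels(dat[[nm]])
    }
  }
  if (ncol(dat) == 0L)
    ns_stop("navsurv_fit_error", "all covariates are zero-variance")
  dat$.y <- as.numeric(records$cohort == "intervention")

  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial())
  )
  cf <- stats::coef(fit)
  na_terms <- names(cf)[is.na(cf)]  # aliased (collinear / empty) columns
  dropped <- c(dropped, na_terms)
  cf <- cf[!is.na(cf)]
  if (!fit$converged)
    ns_stop("navsurv_fit_error",
            "propensity model did not converge after ", fit$iter, " iterations")
  ps <- as.numeric(stats::fitted(fit))
  # Degeneracy is fatal only where it breaks the ATT pipeline: a control
  # patient with ps -> 1 has an exploding SMR weight, and complete
  # separation leaves the model unidentified. A small covariate cell pure
  # in one cohort (ps -> 0 for controls, or ps -> 1 for intervention-only
  # patterns) zeroes or leaves unit weights and is tolerated.
  ctl_hi <- any(ps[records$cohort == "control"] >= 1 - 1e-8)
  complete <- all(ps <= 1e-8 | ps >= 1 - 1e-8)
  if (ctl_hi || complete || any(!is.finite(cf))) {
    worst <- names(cf)[which.max(abs(cf))]
    ns_stop("navsurv_separation_error",
            "perfect or quasi-perfect separation in the propensity model ",
            "(term '", worst, "')")
  }

  structure(list(terms = names(cf), coefficients = cf, ps = ps,
                 dropped_terms = dropped, converged = fit$converged,
                 model = fit),
            class = "propensity_result")
}

#' @export
print.propensity_result <- function(x, ...) {
  cat("Propensity-score model (logistic):", length(x$terms), "terms\n")
  if (length(x$dropped_terms) > 0L)
    cat("  dropped (zero-variance/aliased):",
        paste(x$dropped_terms, collapse = ", "), "\n")
  cat("  PS range:", sprintf("%.4f - %.4f", min(x$ps), max(x$ps)), "\n")
  invisible(x)
}

#' Standardized-mortality-ratio (ATT) weights from propensity scores
#'
#' Weight 1 for every intervention patient; `ps / (1 - ps)` for every
#' control patient, so the weighted control group matches the covariate
#' distribution of the intervention (treated) group — the average treatment
#' effect on the treated.
#'
#' @param ps per-patient propensity scores, strictly inside (0, 1).
#' @param cohort factor/character with levels control / intervention.
#' @param extreme_quantile controls the extreme-weight warning: a warning
#'   is issued when the largest control weight exceeds 10x this quantile of
#'   the control weights. No trimming or truncation is performed.
#' @return numeric vector of nonnegative weights.
#' @export
compute_smr_weights <- function(ps, cohort, extreme_quantile = 0.95) {
  if (any(ps <= 0 | ps >= 1))
    ns_stop("navsurv_domain_error", "propensity scores must lie strictly in (0, 1)")
  intervention <- cohort == "intervention"
  w <- ifelse(intervention, 1, ps / (1 - ps))
  wc <- w[!intervention]
  if (length(wc) > 0L) {
    q <- stats::quantile(wc, extreme_quantile, names = FALSE)
    if (max(wc) > 10 * q)
      warning("extreme SMR weight(s) detected: max = ", signif(max(wc), 4),
              " > 10 x the ", extreme_quantile, " quantile (", signif(q, 4), ")")
  }
  w
}

rubin_moments <- function(x, cohort, weights, scale) {
  if (scale == "logit") x <- stats::qlogis(x)
  if (is.null(weights)) weights <- rep(1, length(x))
  int <- cohort == "intervention"
  if (!any(int) || !any(!int))
    ns_stop("navsurv_domain_error", "both cohorts must be nonempty")
  if (any(weights < 0) || sum(weights[int]) <= 0 || sum(weights[!int]) <= 0)
    ns_stop("navsurv_domain_error", "weights must be nonnegative with positive sum per cohort")
  list(m_int = weighted_mean(x[int], weights[int]),
       m_ctl = weighted_mean(x[!int], weights[!int]),
       v_int = weighted_var(x[int], weights[int]),
       v_ctl = weighted_var(x[!int], weights[!int]))
}

#' Rubin's B: standardized mean difference of propensity scores (percent)
#'
#' `100 * |mean_int - mean_ctl| / sqrt((var_int + var_ctl) / 2)`, with
#' weighted means/variances when weights are supplied (the frequency-
#' consistent variance of [weighted_var()]). B < 25 suggests adequate
#' overall balance. Computed on the PS scale by default, matching the
#' diagnostic's usual description as a statistic "of propensity scores";
#' `scale = "logit"` gives the linearized alternative.
#'
#' @param ps per-patient propensity scores.
#' @param cohort per-patient cohort labels.
#' @param weights optional nonnegative weights.
#' @param scale "ps" (default) or "logit".
#' @return scalar on the percent scale.
#' @export
rubins_b <- function(ps, cohort, weights = NULL, scale = c("ps", "logit")) {
  scale <- match.arg(scale)
  mm <- rubin_moments(ps, cohort, weights, scale)
  denom <- sqrt((mm$v_int + mm$v_ctl) / 2)
  if (denom == 0)
    ns_stop("navsurv_domain_error",
            "zero propensity-score variance in both cohorts: B undefined")
  100 * abs(mm$m_int - mm$m_ctl) / denom
}

#' Rubin's R: variance ratio of propensity scores between cohorts
#'
#' `var_int / var_ctl` with the same weighting conventions as [rubins_b()].
#' Values in `[0.5, 2]` suggest adequate balance.
#'
#' @inheritParams rubins_b
#' @return scalar variance ratio.
#' @export
rubins_r <- function(ps, cohort, weights = NULL, scale = c("ps", "logit")) {
  scale <- match.arg(scale)
  mm <- rubin_moments(ps, cohort, weights, scale)
  if (mm$v_ctl == 0)
    ns_stop("navsurv_domain_error", "zero control propensity-score variance: R undefined")
  mm$v_int / mm$v_ctl
}
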