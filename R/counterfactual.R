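#' Counterfactual g-computation point effect
#'
#' Fits the weighted Cox model with the cohort indicator as the only
#' covariate (the weighting has already balanced the cohorts), then for
#' every intervention-cohort patient predicts survival at each horizon
#' under the factual ("intervention") and counterfactual ("control")
#' settings of the indicator. The effect per horizon is the mean over
#' intervention patients of the individual differences
#' (factual - counterfactual), in probability units.
#'
#' With a single binary covariate this reduces to the closed form
#' `S0(t)^(exp(beta)) - S0(t)` where `S0 = exp(-H0)` is the Breslow
#' baseline (control) survival.
#'
#' @param records validated patient records.
#' @param weights SMR weights from the propensity pipeline.
#' @param horizons prediction horizons in days (default 1/2/3 years as
#'   365, 730, 1095).
#' @param ties tie handling for the Cox fit.
#' @return object of class `counterfactual_estimate` with `horizons`,
#'   `factual`, `counterfactual`, `effect` (all probabilities), and the
#'   underlying `cox_fit`; bootstrap fields are absent.
#' @export
gcomputation_effect <- function(records, weights,
                                horizons = c(365, 730, 1095),
                                ties = "efron") {
  for (coh in c("control", "intervention"))
    if (sum(records$event[records$cohort == coh]) < 1L)
      ns_stop("navsurv_fit_error", "at least one event per cohort is required")
  fit <- fit_weighted_cox(records, weights, terms = "cohort", ties = ties)
  s_factual <- predict_survival(fit, data.frame(cohort = "intervention"), horizons)
  s_counter <- predict_survival(fit, data.frame(cohort = "control"), horizons)
  structure(list(horizons = horizons,
                 factual = s_factual,
                 counterfactual = s_counter,
                 effect = s_factual - s_counter,
                 fit = fit),
            class = "counterfactual_estimate")
}

#' Bootstrap the counterfactual effect
#'
#' Resamples patients with replacement — stratified by cohort by default,
#' preserving the two-sample design and the ATT target — and re-runs the
#' full pipeline inside each replicate exactly as for the original sample:
#' propensity fit, SMR weights, univariate weighted Cox, g-computation.
#' The CI therefore reflects weight-estimation uncertainty. Replicates
#' where the propensity or Cox fit fails are redrawn and counted; more
#' than 5\% failures is a hard error.
#'
#' @param records validated patient records.
#' @param horizons prediction horizons in days.
#' @param n_bootstrap number of replicates (study default 1000).
#' @param seed integer seed; the run is deterministic given it.
#' @param stratified resample within cohort (default TRUE).
#' @param ps_covariates propensity-model covariates (default
#'   [ps_covariates()] intersected with the available columns).
#' @param ties tie handling.
#' @return `counterfactual_estimate` with, per horizon: point and
#'   bootstrap-mean factual/counterfactual survival, point and
#'   bootstrap-mean effect, percentile 95\% CI of the effect and of the
#'   factual/counterfactual survivals, `prob_positive` (fraction of
#'   replicates with effect strictly > 0), the per-replicate effect matrix,
#'   `n_bootstrap`, `seed` and a `failures` count.
#' @export
bootstrap_effect <- function(records, horizons = c(365, 730, 1095),
                             n_bootstrap = 1000L, seed,
                             stratified = TRUE,
                             ps_covariates = intersect(navsurv::ps_covariates(),
                                                       names(records)),
                             ties = "efron") {
  if (n_bootstrap < 1L)
    ns_stop("navsurv_config_error", "n_bootstrap must be >= 1")
  if (missing(seed) || is.null(seed))
    ns_stop("navsurv_config_error", "an integer seed is required")
  set.seed(as.integer(seed))

  run_pipeline <- function(dat) {
    prop <- fit_propensity(dat, covariates = ps_covariates)
    w <- compute_smr_weights(prop$ps, dat$cohort)
    est <- gcomputation_effect(dat, w, horizons, ties = ties)
    list(factual = est$factual, counterfactual = est$counterfactual,
         effect = est$effect)
  }

  point <- suppressWarnings(run_pipeline(records))

  idx_ctl <- which(records$cohort == "control")
  idx_int <- which(records$cohort == "intervention")
  H <- length(horizons)
  eff <- fac <- cfc <- matrix(NA_real_, n_bootstrap, H)
  failures <- 0L
  b <- 1L
  while (b <= n_bootstrap) {
    take <- if (stratified) {
      c(sample(idx_ctl, length(idx_ctl), replace = TRUE),
        sample(idx_int, length(idx_int), replace = TRUE))
    } else {
      sample(nrow(records), nrow(records), replace = TRUE)
    }
    res <- tryCatch(suppressWarnings(run_pipeline(records[take, , drop = FALSE])),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      if (failures > 0.05 * n_bootstrap + 5)
        ns_stop("navsurv_bootstrap_error",
                "more than 5% of bootstrap replicates failed; last error: ",
                conditionMessage(res))
      next
    }
    eff[b, ] <- res$effect; fac[b, ] <- res$factual; cfc[b, ] <- res$counterfactual
    b <- b + 1L
  }
  if (failures > 0.05 * n_bootstrap)
    ns_stop("navsurv_bootstrap_error", failures,
            " of ", n_bootstrap, " bootstrap replicates failed (> 5%)")

  ci <- function(m) apply(m, 2, stats::quantile, probs = c(0.025, 0.975))
  structure(list(horizons = horizons,
                 factual = point$factual,
                 counterfactual = point$counterfactual,
                 effect = point$effect,
                 factual_boot_mean = colMeans(fac),
                 counterfactual_boot_mean = colMeans(cfc),
                 effect_boot_mean = colMeans(eff),
                 ci95_effect = ci(eff),
                 ci95_factual = ci(fac),
                 ci95_counterfactual = ci(cfc),
                 prob_positive = colMeans(eff > 0),
                 replicate_effects = eff,
                 n_bootstrap = n_bootstrap, seed = as.integer(seed),
                 stratified = stratified, failures = failures),
            class = "counterfactual_estimate")
}

#' @export
print.counterfactual_estimate <- function(x, ...) {
  cat("Counterfactual g-computation of overall survival\n")
  yr <- x$horizons / 365
  hdr <- sprintf("%g-year", yr)
  cat("  point factual       :", paste(sprintf("%s %.1f%%", hdr, 100 * x$factual),
                                        collapse = "  "), "\n")
  cat("  point counterfactual:", paste(sprintf("%s %.1f%%", hdr, 100 * x$counterfactual),
                                        collapse = "  "), "\n")
  cat("  point effect        :", paste(sprintf("%s %+.1f pp", hdr, 100 * x$effect),
                                        collapse = "  "), "\n")
  if (!is.null(x$n_bootstrap)) {
    cat(sprintf("  bootstrap (%d replicates, %d failed redrawn):\n",
                x$n_bootstrap, x$failures))
    for (i in seq_along(yr)) {
      cat(sprintf("    %s effect %+.1f pp [%.1f, %.1f], P(effect > 0) = %.1f%%\n",
                  hdr[i], 100 * x$effect_boot_mean[i],
                  100 * x$ci95_effect[1, i], 100 * x$ci95_effect[2, i],
                  100 * x$prob_positive[i]))
    }
  }
  invisible(x)
}

#' Export a counterfactual estimate as a horizon table
#' @param est a `counterfactual_estimate` (with bootstrap fields).
#' @return data frame, rows = quantity, columns = horizons; percentages.
#' @export
counterfactual_table <- function(est) {
  stopifnot(!is.null(est$n_bootstrap))
  out <- rbind(
    intervention = 100 * est$factual_boot_mean,
    counterfactual = 100 * est$counterfactual_boot_mean,
    effect = 100 * est$effect_boot_mean,
    effect_point = 100 * est$effect,
    ci_low = 100 * est$ci95_effect[1, ],
    ci_high = 100 * est$ci95_effect[2, ],
    prob_positive = 100 * est$prob_positive
  )
  colnames(out) <- sprintf("day_%d", est$horizons)
  as.data.frame(out)
}
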