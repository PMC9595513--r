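#' Weighted Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod_{t_i <= t} (1 - d_w(t_i) / n_w(t_i))` with weighted event
#' and at-risk sums. Censored-only times leave the curve unchanged.
#' Duplicating a patient and doubling its weight give identical curves
#' (weight-frequency equivalence); unit weights give the classical
#' product-limit estimator.
#'
#' @param times follow-up times (days).
#' @param events 0/1 death indicators.
#' @param weights nonnegative weights (default 1).
#' @param label optional cohort label carried on the result.
#' @return object of class `km_curve`: data frame with `time` (distinct
#'   event times, increasing), `at_risk_weighted` (weighted number at risk
#'   just before the time), `events_weighted`, `survival`.
#' @export
weighted_km <- function(times, events, weights = NULL, label = NULL) {
  n <- length(times)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(events) == n, length(weights) == n)
  if (any(weights < 0))
    ns_stop("navsurv_domain_error", "weights must be nonnegative")
  dt <- sort(unique(times[events == 1 & weights > 0]))
  surv <- numeric(length(dt))
  atrisk <- numeric(length(dt))
  dw <- numeric(length(dt))
  s <- 1
  for (i in seq_along(dt)) {
    t0 <- dt[i]
    nw <- sum(weights[times >= t0])
    d <- sum(weights[times == t0 & events == 1])
    s <- s * (1 - d / nw)
    surv[i] <- s; atrisk[i] <- nw; dw[i] <- d
  }
  structure(data.frame(time = dt, at_risk_weighted = atrisk,
                       events_weighted = dw, survival = surv),
            label = label, n = n, sum_weights = sum(weights),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step-function convention: the value at `t` uses all
#' event times `<= t`.
#' @param km a [weighted_km()] curve.
#' @param t times (days).
#' @return survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- findInterval(tt, km$time)
    if (i == 0L) 1 else km$survival[i]
  }, numeric(1))
}

#' Weighted log-rank test
#'
#' Default `variant = "robust"`: the robust score test of the weighted
#' single-covariate Cox model, which accounts for the weights being
#' estimated rather than frequencies. `variant = "naive"` computes the
#' classical log-rank sums on weighted event/at-risk counts with the
#' hypergeometric variance; with unit weights it equals the classical
#' log-rank test.
#'
#' @param times follow-up times.
#' @param events 0/1 death indicators.
#' @param weights nonnegative weights (default 1).
#' @param group two-level group labels.
#' @param variant "robust" (default) or "naive".
#' @return list with `chi2`, `p`, `df` (= 1), `variant`.
#' @export
weighted_logrank <- function(times, events, weights = NULL, group,
                             variant = c("robust", "naive")) {
  variant <- match.arg(variant)
  if (is.null(weights)) weights <- rep(1, length(times))
  g <- factor(group)
  if (nlevels(droplevels(g)) != 2L)
    ns_stop("navsurv_domain_error", "exactly two nonempty groups are required")
  if (variant == "robust") {
    fit <- survival::coxph(survival::Surv(times, events) ~ g,
                           weights = weights, robust = TRUE)
    chi2 <- as.numeric(fit$rscore)
  } else {
    g2 <- g == levels(droplevels(g))[2L]
    dt <- sort(unique(times[events == 1 & weights > 0]))
    o_minus_e <- 0; v <- 0
    for (t0 in dt) {
      at <- times >= t0
      nw <- sum(weights[at])
      n2 <- sum(weights[at & g2])
      d <- sum(weights[times == t0 & events == 1])
      d2 <- sum(weights[times == t0 & events == 1 & g2])
      o_minus_e <- o_minus_e + (d2 - d * n2 / nw)
      if (nw > 1)
        v <- v + d * (n2 / nw) * (1 - n2 / nw) * (nw - d) / (nw - 1)
    }
    if (v <= 0)
      ns_stop("navsurv_domain_error", "log-rank variance is zero")
    chi2 <- o_minus_e^2 / v
  }
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L, variant = variant)
}

#' Canonical Cox model term sets
#'
#' Three specifications: `univariate` (cohort indicator only); `baseline`
#' (cohort + every baseline covariate, histology included as a baseline
#' characteristic because it is time-invariant even though unknown at day
#' 0); `post_baseline` (cohort + completed-investigation indicators,
#' tumor-board recommendation, treatment modalities, and stage/ECOG at
#' treatment initiation — chest CT does not appear as a pre-treatment
#' variable). Reference levels follow the covariate dictionary: onset =
#' asymptomatic (accidental finding), stage = I, ECOG = 0, histology =
#' adenocarcinoma, delay class = q1 (0-13 days).
#'
#' @return named list of character term vectors.
#' @export
model_specifications <- function() {
  list(
    univariate = "cohort",
    baseline = c("cohort", baseline_covariates()),
    post_baseline = c("cohort", post_baseline_covariates())
  )
}

#' Weighted Cox proportional-hazards fit with robust variance
#'
#' Maximizes the weighted Cox partial likelihood (weights multiply the
#' individual score contributions; Efron tie handling by default) via
#' `survival::coxph`, reporting the robust sandwich variance by default
#' because SMR weights are estimated, not frequencies. Constant covariates
#' are dropped with a record, mirroring the propensity model; aliased
#' (collinear) or monotone-likelihood terms raise explicit errors. The
#' Breslow baseline cumulative hazard at the reference covariate pattern is
#' computed and stored for survival prediction.
#'
#' @param records validated patient records.
#' @param weights nonnegative per-patient weights.
#' @param terms covariate names to include (e.g. an element of
#'   [model_specifications()]).
#' @param ties "efron" (default) or "breslow".
#' @param robust use the sandwich variance (default TRUE).
#' @return object of class `cox_fit`: `terms` (model-matrix column names),
#'   `log_hr`, `se` (robust by default), `hr`, `ci_lower`, `ci_upper`, `p`
#'   (Wald), `ties`, `baseline_cumhaz` (data frame `time`, `cumhaz`),
#'   `loglik`, `dropped_terms`, plus the underlying `coxph` fit.
#' @export
fit_weighted_cox <- function(records, weights = NULL, terms = "cohort",
                             ties = c("efron", "breslow"), robust = TRUE) {
  ties <- match.arg(ties)
  n <- nrow(records)
  if (is.null(weights)) weights <- rep(1, n)
  if (sum(records$event) < 1L)
    ns_stop("navsurv_fit_error", "at least one event is required")
  dat <- records[, terms, drop = FALSE]
  dropped <- character(0)
  for (nm in terms) {
    x <- dat[[nm]]
    if (is.factor(x)) x <- droplevels(x)
    constant <- if (is.factor(x)) nlevels(x) < 2L else stats::var(as.numeric(x)) == 0
    if (constant) { dropped <- c(dropped, nm); dat[[nm]] <- NULL }
    else if (is.factor(dat[[nm]])) dat[[nm]] <- droplevels(dat[[nm]])
  }
  if (ncol(dat) == 0L)
    ns_stop("navsurv_fit_error", "all model terms are zero-variance")
  dat$.time <- records$followup_days
  dat$.event <- records$event
  dat$.w <- weights

  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", setdiff(names(dat), c(".time", ".event", ".w"))),
          collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, weights = .w, ties = ties,
                    robust = robust, model = TRUE, x = TRUE),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge",
                conditionMessage(w)))
        ns_stop("navsurv_fit_error",
                "monotone likelihood / non-convergence in Cox fit: ",
                conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (anyNA(cf))
    ns_stop("navsurv_fit_error", "collinear Cox term(s): ",
            paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  se_col <- if (robust) "robust se" else "se(coef)"
  se <- sm[, se_col]
  ci_l <- exp(cf - 1.96 * se)
  ci_u <- exp(cf + 1.96 * se)
  p <- 2 * stats::pnorm(-abs(cf / se))

  # Breslow baseline cumulative hazard at the reference pattern:
  # H0(t) = sum_{tj <= t} sum(w_deaths at tj) / sum_{risk set} w_i exp(lp_i)
  x <- fit$x
  lp <- as.numeric(x %*% cf)
  o <- order(dat$.time)
  tt <- dat$.time[o]; ev <- dat$.event[o]; w <- dat$.w[o]
  we <- w * exp(lp[o])
  risk_from <- rev(cumsum(rev(we)))          # sum of w*exp(lp) over {t_j >= t_i}
  first <- which(!duplicated(tt))
  ut <- tt[first]
  risk_u <- risk_from[first]
  death_u <- as.numeric(rowsum(w * ev, tt))  # weighted deaths per distinct time
  keep <- death_u > 0
  basehaz <- data.frame(time = ut[keep],
                        cumhaz = cumsum(death_u[keep] / risk_u[keep]))

  structure(list(terms = names(cf), log_hr = cf, se = se, hr = exp(cf),
                 ci_lower = ci_l, ci_upper = ci_u, p = p, ties = ties,
                 robust = robust, baseline_cumhaz = basehaz,
                 loglik = fit$loglik[length(fit$loglik)],
                 dropped_terms = dropped, n = n, nevent = sum(records$event),
                 xlevels = fit$xlevels, formula_terms = stats::delete.response(fit$terms),
                 assign_names = colnames(x), fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Weighted Cox PH fit (%s ties, %s variance): n = %d, events = %d\n",
              x$ties, if (x$robust) "robust" else "model-based", x$n, x$nevent))
  df <- data.frame(term = x$terms, HR = round(x$hr, 2),
                   ci95 = sprintf("[%.2f-%.2f]", x$ci_lower, x$ci_upper),
                   p = signif(x$p, 2))
  print.data.frame(df, row.names = FALSE)
  if (length(x$dropped_terms))
    cat("  dropped zero-variance term(s):", paste(x$dropped_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Export a Cox fit as a hazard-ratio table
#' @param fit a `cox_fit`.
#' @return data frame with term, HR, CI bounds and Wald p.
#' @export
cox_table <- function(fit) {
  data.frame(term = fit$terms, hr = fit$hr, ci_lower = fit$ci_lower,
             ci_upper = fit$ci_upper, p = fit$p, row.names = NULL)
}

#' Predict survival from a weighted Cox fit
#'
#' `S(t | x) = exp(-H0(t))^(exp(x beta))` with the stored Breslow baseline
#' cumulative hazard; right-continuous step convention (the value at `t`
#' uses all event times `<= t`). Times beyond the last observed event time
#' return the last step with an extrapolation warning.
#'
#' @param fit a `cox_fit`.
#' @param covariates one-row data frame (or named list) giving the
#'   covariate pattern, coded as in the fit's data.
#' @param t days (vectorized), `t >= 0`.
#' @return survival probabilities.
#' @export
predict_survival <- function(fit, covariates, t) {
  if (any(t < 0)) ns_stop("navsurv_domain_error", "t must be nonnegative")
  nd <- as.data.frame(covariates, stringsAsFactors = FALSE)
  for (nm in names(fit$xlevels))
    nd[[nm]] <- factor(nd[[nm]], levels = fit$xlevels[[nm]])
  mm <- stats::model.matrix(fit$formula_terms, nd, xlev = fit$xlevels)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  mm <- mm[, fit$terms, drop = FALSE]
  lp <- as.numeric(mm %*% fit$log_hr)
  bh <- fit$baseline_cumhaz
  tmax <- if (nrow(bh) > 0L) max(bh$time) else 0
  if (any(t > tmax))
    warning("extrapolating survival beyond the last observed event time (",
            tmax, " days)")
  h0 <- vapply(t, function(tt) {
    i <- findInterval(tt, bh$time)
    if (i == 0L) 0 else bh$cumhaz[i]
  }, numeric(1))
  exp(-h0 * exp(lp))
}
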