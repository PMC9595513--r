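# Weighted ranks with frequency semantics: a record of weight w occupies w
# consecutive rank slots; its average rank is cumw_before + (w + 1) / 2.
# With unit weights this equals rank(x, ties.method = "average").
weighted_ranks <- function(x, w) {
  o <- order(x)
  xo <- x[o]; wo <- w[o]
  r <- numeric(length(x))
  cw <- 0
  i <- 1L
  while (i <= length(xo)) {
    j <- i
    while (j < length(xo) && xo[j + 1L] == xo[i]) j <- j + 1L
    gw <- sum(wo[i:j])
    r[o[i:j]] <- cw + (gw + 1) / 2
    cw <- cw + gw
    i <- j + 1L
  }
  r
}

# Design-based Kruskal-Wallis on weighted ranks: weights are rescaled so
# their total equals the Kish effective sample size, then the classical
# H statistic is computed with weighted rank sums. Unit weights reproduce
# stats::kruskal.test (without its tie correction beyond average ranks).
weighted_kruskal_test <- function(x, group, w = NULL) {
  keep <- !is.na(x)
  x <- x[keep]; group <- droplevels(factor(group[keep]))
  w <- if (is.null(w)) rep(1, length(x)) else w[keep]
  w <- w * effective_n(w) / sum(w)
  W <- sum(w)
  r <- weighted_ranks(x, w)
  h <- 0
  for (g in levels(group)) {
    idx <- group == g
    h <- h + sum(w[idx] * r[idx])^2 / sum(w[idx])
  }
  h <- 12 / (W * (W + 1)) * h - 3 * (W + 1)
  # tie correction as in the classical test
  tie_sizes <- tapply(w, x, sum)
  corr <- 1 - sum(tie_sizes^3 - tie_sizes) / (W^3 - W)
  if (corr > 0) h <- h / corr
  df <- nlevels(group) - 1L
  list(statistic = h, df = df,
       p.value = stats::pchisq(h, df, lower.tail = FALSE))
}

#' Treatment-delay summary by cohort
#'
#' Weighted median and weighted IQR (inverse-CDF, lower-value convention:
#' the smallest value whose cumulative normalized weight reaches the target
#' fraction) of the delay from first cancer-suspect code to treatment
#' initiation, per cohort, with a design-based Kruskal-Wallis p-value for
#' the between-cohort comparison. Untreated patients (missing delay) are
#' excluded and counted.
#'
#' @param records validated patient records.
#' @param weights per-patient weights (default 1).
#' @return data frame rows (variable, cohort, n_treated, n_untreated,
#'   median, q1, q3, p); empty with a `note` attribute when no patient was
#'   treated.
#' @export
summarize_delays <- function(records, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(records))
  treated <- !is.na(records$treatment_delay_days)
  if (!any(treated)) {
    out <- data.frame()
    attr(out, "note") <- "no treated patients: delay table empty"
    return(out)
  }
  kw <- weighted_kruskal_test(records$treatment_delay_days[treated],
                              records$cohort[treated], weights[treated])
  rows <- lapply(levels(records$cohort), function(coh) {
    idx <- treated & records$cohort == coh
    q <- weighted_quantile(records$treatment_delay_days[idx], weights[idx],
                           c(0.25, 0.5, 0.75))
    data.frame(variable = "treatment_delay_days", cohort = coh,
               n_treated = sum(idx),
               n_untreated = sum(records$cohort == coh) - sum(idx),
               q1 = q[1], median = q[2], q3 = q[3], p = kw$p.value)
  })
  do.call(rbind, rows)
}

#' Process, treatment and intermediate-outcome summary by cohort
#'
#' Weighted proportions per cohort for every process indicator, treatment
#' modality, and stage/ECOG level, with design-based chi-squared p-values,
#' plus the early-vs-advanced stage-ratio descriptive
#' (\% stage I+II divided by \% stage IV) per cohort.
#'
#' @param records validated patient records.
#' @param weights per-patient weights (default 1: unweighted table).
#' @return data frame rows (variable, level, control, intervention, p) with
#'   proportions on the percent scale; attribute `weighted` records whether
#'   non-unit weights were used.
#' @export
summarize_process_and_outcomes <- function(records, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(records))
  int <- records$cohort == "intervention"
  dict <- covariate_dictionary()
  rows <- list()
  for (nm in post_baseline_covariates()) {
    sp <- dict[[nm]]
    x <- records[[nm]]
    xf <- if (sp$kind == "binary") factor(x, levels = c(0, 1)) else x
    lev <- if (sp$kind == "binary") "1" else sp$levels
    p <- weighted_chisq_test(xf, records$cohort, weights)
    for (l in lev) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, level = l,
        control = 100 * weighted_mean(as.numeric(xf[!int] == l), weights[!int]),
        intervention = 100 * weighted_mean(as.numeric(xf[int] == l), weights[int]),
        p = p)
    }
  }
  out <- do.call(rbind, rows)
  stage_pct <- function(side_idx, lv) {
    100 * weighted_mean(as.numeric(records$stage_at_tx[side_idx] %in% lv),
                        weights[side_idx])
  }
  ratio <- data.frame(
    variable = "stage_ratio_I_II_over_IV", level = "ratio",
    control = stage_pct(!int, c("I", "II")) / stage_pct(!int, "IV"),
    intervention = stage_pct(int, c("I", "II")) / stage_pct(int, "IV"),
    p = NA_real_)
  out <- rbind(out, ratio)
  attr(out, "weighted") <- !all(weights == 1)
  out
}
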