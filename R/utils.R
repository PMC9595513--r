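#' Weighted mean
#'
#' @param x numeric vector.
#' @param w nonnegative weights, recycled to `length(x)`.
#' @return scalar weighted mean.
#' @keywords internal
weighted_mean <- function(x, w = NULL) {
  if (is.null(w)) return(mean(x))
  stopifnot(length(w) == length(x), all(w >= 0), sum(w) > 0)
  sum(w * x) / sum(w)
}

#' Weighted variance (frequency-consistent)
#'
#' Uses the estimator sum(w * (x - xbar)^2) / sum(w), i.e. no small-sample
#' correction. With unit weights this is the population variance (divisor n).
#' This convention keeps Rubin's B/R stable under uniform weight rescaling
#' and matches the large-sample diagnostic use of these statistics.
#'
#' @inheritParams weighted_mean
#' @keywords internal
weighted_var <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  m <- weighted_mean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

#' Weighted quantile (inverse-CDF, lower-value convention)
#'
#' Returns the smallest observed value whose cumulative normalized weight
#' reaches the target fraction. With unit weights and odd n this is the
#' sample median at p = 0.5.
#'
#' @param x numeric vector.
#' @param w nonnegative weights.
#' @param probs target fractions in `[0, 1]`.
#' @return numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w = NULL, probs = c(0.25, 0.5, 0.75)) {
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(w) == length(x), all(w >= 0), all(probs >= 0 & probs <= 1))
  keep <- !is.na(x)
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) return(rep(NA_real_, length(probs)))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

#' Kish effective sample size
#'
#' (sum w)^2 / sum(w^2); equals n for unit weights. Used to calibrate
#' design-based tests on weighted data.
#' @keywords internal
effective_n <- function(w) sum(w)^2 / sum(w^2)

#' Derive reproducible sub-seeds from one master seed
#'
#' A single user-facing seed governs every source of randomness in a run.
#' Stage-level seeds are drawn from a stream seeded by the master seed, so
#' stage-level reruns reproduce the corresponding slice of a full run.
#' All sub-seeds are kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @export
seed_streams <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

# internal: stop() with a classed condition so callers can test error types
ns_stop <- function(class, ...) {
  stop(structure(class = c(class, "navsurv_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
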