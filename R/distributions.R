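#' Probabilistic-sensitivity-analysis distributions
#'
#' The PSA represents second-order (parameter) uncertainty with beta
#' distributions for probabilities and utilities and gamma distributions for
#' costs, each moment-matched to the base case: the fitted mean equals the
#' base-case value and the fitted standard deviation is
#' `(high - low) / (2 * 1.96)`, treating the printed interval as a
#' normal-approximation 95% range. A degenerate interval collapses to a
#' point mass.
#'
#' @name psa_dist
#' @examples
#' d <- beta_from_mean_ci(0.079, 0.064, 0.095)
#' psa_mean(d)
NULL

new_psa_dist <- function(family, mean, ...) {
  structure(c(list(family = family, mean = mean), list(...)), class = "psa_dist")
}

#' @export
print.psa_dist <- function(x, ...) {
  extra <- switch(x$family,
    beta = sprintf(" (shape1 %.4g, shape2 %.4g)", x$shape1, x$shape2),
    gamma = sprintf(" (shape %.4g, scale %.4g)", x$shape, x$scale),
    "")
  cat(sprintf("psa_dist: %s, mean %.6g%s\n", x$family, x$mean, extra))
  invisible(x)
}

#' Fit a beta distribution from a mean and 95% interval
#'
#' Moment matching: the interval half-width divided by 1.96 gives the
#' standard deviation; shape parameters follow from the mean/variance
#' identities of the beta family. If the implied variance is infeasible
#' (`var >= mean * (1 - mean)`) the fit fails rather than silently
#' truncating.
#'
#' @param mean Base-case probability, strictly inside (0, 1) unless the
#'   interval is degenerate.
#' @param ci_low,ci_high Interval bounds.
#' @return A `psa_dist` of family `"beta"` (or `"point"` when
#'   `ci_low == ci_high`).
#' @export
beta_from_mean_ci <- function(mean, ci_low, ci_high) {
  if (ci_low > ci_high) stop("ci_low > ci_high", call. = FALSE)
  if (ci_low == ci_high) return(new_psa_dist("point", mean))
  if (mean <= 0 || mean >= 1) {
    stop("beta fit requires 0 < mean < 1, got ", mean, call. = FALSE)
  }
  sdev <- (ci_high - ci_low) / (2 * 1.96)
  v <- sdev^2
  if (v >= mean * (1 - mean)) {
    stop("implied variance ", signif(v, 6), " infeasible for a beta with mean ",
         mean, call. = FALSE)
  }
  k <- mean * (1 - mean) / v - 1
  new_psa_dist("beta", mean, shape1 = mean * k, shape2 = (1 - mean) * k, sd = sdev)
}

#' Fit a gamma distribution from a mean and range
#'
#' Method of moments with `sd = (high - low) / (2 * 1.96)`:
#' `shape = mean^2 / var`, `scale = var / mean`.
#'
#' @param mean Base-case cost, strictly positive unless the range is
#'   degenerate.
#' @param low,high Range bounds.
#' @return A `psa_dist` of family `"gamma"` (or `"point"` when
#'   `low == high`).
#' @export
gamma_from_mean_range <- function(mean, low, high) {
  if (low > high) stop("low > high", call. = FALSE)
  if (low == high) return(new_psa_dist("point", mean))
  if (mean <= 0) stop("gamma fit requires mean > 0, got ", mean, call. = FALSE)
  sdev <- (high - low) / (2 * 1.96)
  v <- sdev^2
  new_psa_dist("gamma", mean, shape = mean^2 / v, scale = v / mean, sd = sdev)
}

#' Mean of a fitted PSA distribution
#' @param d A `psa_dist`.
#' @return The analytic mean of the fitted distribution.
#' @export
psa_mean <- function(d) {
  stopifnot(inherits(d, "psa_dist"))
  switch(d$family,
         point = d$mean,
         beta = d$shape1 / (d$shape1 + d$shape2),
         gamma = d$shape * d$scale)
}

#' Draw from a fitted PSA distribution
#'
#' Uses the current R random-number stream; seed management belongs to the
#' caller ([run_psa()] seeds once per run).
#'
#' @param d A `psa_dist`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
psa_sample <- function(d, n = 1) {
  stopifnot(inherits(d, "psa_dist"))
  switch(d$family,
         point = rep(d$mean, n),
         beta = stats::rbeta(n, d$shape1, d$shape2),
         gamma = stats::rgamma(n, shape = d$shape, scale = d$scale))
}

#' Fit PSA distributions for every uncertain parameter of a model
#'
#' Probabilities and utilities are matched with [beta_from_mean_ci()], costs
#' with [gamma_from_mean_range()]; a parameter with a degenerate range (or a
#' structural zero such as the no-AKI 30-day ESRD probability) becomes a
#' point mass.
#'
#' @param m An `aki_model`.
#' @return Named list of `psa_dist`, one per row of [param_table()].
#' @export
fit_psa_distributions <- function(m) {
  p <- param_table(m)
  out <- vector("list", nrow(p))
  names(out) <- p$id
  for (i in seq_len(nrow(p))) {
    out[[i]] <- if (p$low[i] == p$high[i]) {
      new_psa_dist("point", p$value[i])
    } else if (p$family[i] == "beta") {
      beta_from_mean_ci(p$value[i], p$low[i], p$high[i])
    } else {
      gamma_from_mean_range(p$value[i], p$low[i], p$high[i])
    }
  }
  out
}
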