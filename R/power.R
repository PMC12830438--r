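# Sample-size planning for DI-based designs: per-group n for between-group
# comparisons via the noncentral-t power function, and n for detecting a
# target correlation via the Fisher-z approximation.

#' Power of a two-group t test at a given per-group n
#'
#' Exact power from the noncentral-t distribution for an independent-samples
#' t test with per-group size `n` and standardised effect
#' `d = delta / sigma` (noncentrality `d * sqrt(n/2)`, df `2n - 2`).
#'
#' @param n per-group sample size (>= 2).
#' @param delta raw group difference, in DI-rate units.
#' @param sigma between-subject SD of the DI rate.
#' @param alpha significance level.
#' @param tails `"two"` or `"one"`.
#' @return the power, a probability. Depends on `delta` and `sigma` only
#'   through their ratio.
#' @export
power_two_group <- function(n, delta, sigma, alpha = 0.05,
                            tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  d <- delta / sigma
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (tails == "two") {
    tc <- qt(1 - alpha / 2, df)
    pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
  } else {
    pt(qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
  }
}

#' Smallest per-group n for a between-group DI comparison
#'
#' Iterates the noncentral-t power function over n and returns the smallest
#' integer per-group sample size whose power reaches the target.
#'
#' @inheritParams power_two_group
#' @param power target power in (0, 1).
#' @param n_cap upper bound on the search; if the requirement exceeds it the
#'   result is `NA` with attribute `capped = TRUE` and a warning.
#' @return smallest integer n per group.
#' @export
#' @examples
#' n_per_group(delta = 0.10, sigma = 0.23)  # the paper-scale planning case
n_per_group <- function(delta, sigma, power = 0.80, alpha = 0.05,
                        tails = c("two", "one"), n_cap = 1e6) {
  tails <- match.arg(tails)
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  # bracket by doubling, then binary-search the smallest achieving n
  lo <- 2L; hi <- 2L
  while (power_two_group(hi, delta, sigma, alpha, tails) < power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > n_cap) {
      warning("required n exceeds n_cap; result capped", call. = FALSE)
      return(structure(NA_integer_, capped = TRUE))
    }
  }
  while (hi > lo + 1L) {
    mid <- (lo + hi) %/% 2L
    if (power_two_group(mid, delta, sigma, alpha, tails) >= power)
      hi <- mid else lo <- mid
  }
  if (power_two_group(lo, delta, sigma, alpha, tails) >= power) lo else hi
}

#' Power to detect a correlation (Fisher-z approximation)
#'
#' `Phi(sqrt(n - 3) * atanh(rho) - z_crit)` for the requested tails.
#'
#' @param n sample size (>= 4).
#' @param rho population correlation, 0 < |rho| < 1.
#' @inheritParams power_two_group
#' @return the approximate power.
#' @export
power_correlation <- function(n, rho, alpha = 0.05, tails = c("two", "one")) {
  tails <- match.arg(tails)
  zc <- if (tails == "two") qnorm(1 - alpha / 2) else qnorm(1 - alpha)
  pnorm(sqrt(n - 3) * atanh(abs(rho)) - zc)
}

#' Smallest n to detect a target correlation
#'
#' Iterates the Fisher-z power approximation and returns the smallest
#' integer n reaching the target power. Approximations to this quantity
#' differ across tools, so the method is recorded in the result.
#'
#' @inheritParams power_correlation
#' @inheritParams n_per_group
#' @return smallest integer n, with attribute `method = "fisher_z"`.
#' @export
#' @examples
#' n_for_correlation(0.40, tails = "one")  # 38 under the Fisher-z method
n_for_correlation <- function(rho, power = 0.80, alpha = 0.05,
                              tails = c("two", "one"), n_cap = 1e6) {
  tails <- match.arg(tails)
  if (abs(rho) <= 0 || abs(rho) >= 1)
    stop("rho must satisfy 0 < |rho| < 1", call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)", call. = FALSE)
  n <- 4L
  while (power_correlation(n, rho, alpha, tails) < power) {
    n <- n + 1L
    if (n > n_cap) {
      warning("required n exceeds n_cap; result capped", call. = FALSE)
      return(structure(NA_integer_, capped = TRUE, method = "fisher_z"))
    }
  }
  structure(n, method = "fisher_z")
}

#' Per-group sample-size curve over a grid of group differences
#'
#' Vectorises [n_per_group()] over a delta grid for both one- and two-tailed
#' hypotheses. The one-tailed curve lies at or below the two-tailed curve
#' everywhere, and both are nonincreasing in delta.
#'
#' @param deltas raw group differences to scan.
#' @inheritParams n_per_group
#' @return a data frame of class `power_curve` with columns `delta`,
#'   `n_one_tailed`, `n_two_tailed`.
#' @export
#' @examples
#' power_curve(c(.05, .10, .15, .20), sigma = 0.23)
power_curve <- function(deltas, sigma = 0.23, power = 0.80, alpha = 0.05) {
  out <- data.frame(
    delta = deltas,
    n_one_tailed = vapply(deltas, function(d)
      as.integer(n_per_group(d, sigma, power, alpha, "one")), integer(1)),
    n_two_tailed = vapply(deltas, function(d)
      as.integer(n_per_group(d, sigma, power, alpha, "two")), integer(1)))
  structure(out, class = c("power_curve", "data.frame"),
            sigma = sigma, power = power, alpha = alpha)
}
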