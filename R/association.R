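# Association statistics: Pearson / partial correlations, the Fisher r-to-z
# comparison of two independent correlations, Bayes factors for correlations
# under a stretched beta prior, the JZS t-test Bayes factor, and the
# task-order correction for counterbalanced designs.

#' Pearson correlation with test
#'
#' Product-moment correlation on pairwise-complete cases with a two-sided p
#' value from the t transform. Reported with df = n - 2, matching the
#' conventional `r(df)` notation.
#'
#' @param x,y numeric vectors.
#' @return an object of class `correlation_result`: `r`, `n`, `df`, `p`.
#' @export
#' @examples
#' cor_pearson(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
cor_pearson <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- cor.test(x, y)
  structure(list(r = unname(ct$estimate), n = n, df = n - 2L,
                 p = ct$p.value), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  p <- if (x$p < .001) "p < .001" else sprintf("p = %.3f", x$p)
  extra <- if (!is.null(x$controlling))
    sprintf(" (partial, controlling %s)", x$controlling) else ""
  cat(sprintf("r(%d) = %.3f, %s%s\n", x$df, x$r, p, extra))
  invisible(x)
}

#' Partial correlation controlling for one covariate
#'
#' First-order partial correlation
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' with df = n - 3 and a two-sided p from the t transform.
#'
#' @param x,y variables of interest.
#' @param z covariate to partial out.
#' @param z_name label recorded in the result.
#' @return a `correlation_result` with `r_partial` semantics
#'   (`controlling` records the covariate).
#' @export
cor_partial <- function(x, y, z, z_name = deparse(substitute(z))) {
  ok <- complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete triples", call. = FALSE)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("covariate collinear with a variable: partial correlation undefined",
         call. = FALSE)
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  df <- n - 3L
  tt <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, n = n, df = df, p = 2 * pt(-abs(tt), df),
                 controlling = z_name), class = "correlation_result")
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' `Z = (atanh(r2) - atanh(r1)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p value. Antisymmetric in the two samples.
#'
#' @param r1,n1 first correlation and its sample size.
#' @param r2,n2 second correlation and its sample size.
#' @return a list with `Z` and `p`.
#' @export
#' @examples
#' compare_correlations_fisher(.25, 97, .26, 99)  # Z = 0.07, p = .94
compare_correlations_fisher <- function(r1, n1, r2, n2) {
  for (v in list(r1, r2)) if (abs(v) >= 1)
    stop("|r| must be < 1 for the z transform", call. = FALSE)
  if (n1 <= 3 || n2 <= 3) stop("both samples must have n > 3", call. = FALSE)
  z <- (atanh(r2) - atanh(r1)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(Z = z, p = 2 * pnorm(-abs(z)))
}

# Gauss hypergeometric 2F1(a, b; c; x) by power series, valid for 0 <= x < 1
# with c > a + b (always true here: c grows with n). Relative tolerance 1e-12.
.hyp2f1 <- function(a, b, cc, x) {
  term <- 1; s <- 1
  for (k in 0:20000) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * x
    s <- s + term
    if (abs(term) < 1e-12 * abs(s)) return(s)
  }
  stop("hypergeometric series failed to converge", call. = FALSE)
}

# log of the rho-dependent part of the sampling density of the Pearson
# correlation r under bivariate normality (hypergeometric-series form).
.log_lik_rho <- function(rho, r, n) {
  (n - 1) / 2 * log1p(-rho^2) + (3 - 2 * n) / 2 * log1p(-rho * r) +
    log(.hyp2f1(0.5, 0.5, n - 0.5, (1 + rho * r) / 2))
}

# stretched beta prior density on (-1, 1): Beta(1/kappa, 1/kappa) rescaled;
# kappa = 1 is uniform.
.stretched_beta <- function(rho, kappa) {
  dbeta((rho + 1) / 2, 1 / kappa, 1 / kappa) / 2
}

#' Bayes factor for a Pearson correlation under a stretched beta prior
#'
#' Computes `BF10 = integral f(r | rho, n) pi_k(rho) d rho / f(r | 0, n)`
#' where `f` is the exact sampling density of the sample correlation under
#' bivariate normality and `pi_k` is a beta prior stretched to (-1, 1) with
#' width `kappa` (`kappa = 1` is uniform, the default in common Bayesian
#' software). For directional hypotheses the prior is truncated to the
#' requested half-line and renormalised. Integration is performed on the log
#' scale, so large-n Bayes factors do not overflow.
#'
#' @param r observed sample correlation, |r| < 1.
#' @param n sample size (>= 3).
#' @param direction `"two_sided"` (default), `"positive"` or `"negative"`.
#' @param kappa prior width (> 0).
#' @return an object of class `bayes_factor` with fields `bf10`, `bf01`,
#'   `direction`, `kappa`.
#' @export
#' @examples
#' bf_cor(0.4, 38, direction = "positive")
bf_cor <- function(r, n, direction = c("two_sided", "positive", "negative"),
                   kappa = 1.0) {
  direction <- match.arg(direction)
  .stopifnot_scalar(r, "r"); .stopifnot_scalar(n, "n")
  if (abs(r) >= 1) stop("|r| must be < 1", call. = FALSE)
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)

  lims <- switch(direction,
                 two_sided = c(-1, 1), positive = c(0, 1), negative = c(-1, 0))
  prior_mass <- 0.5 + 0.5 * (direction == "two_sided")
  log_l0 <- .log_lik_rho(0, r, n)
  # peak of the log likelihood-ratio over the integration range, for scaling
  opt <- optimize(function(rho) .log_lik_rho(rho, r, n),
                  interval = lims, maximum = TRUE)
  m <- max(opt$objective - log_l0, 0)
  integrand <- function(rho)
    vapply(rho, function(p)
      exp(.log_lik_rho(p, r, n) - log_l0 - m), numeric(1)) *
      .stretched_beta(rho, kappa) / prior_mass
  quad <- integrate(integrand, lims[1], lims[2], rel.tol = 1e-6,
                    stop.on.error = FALSE)
  if (quad$message != "OK" || !is.finite(quad$value) || quad$value <= 0)
    stop("Bayes factor quadrature failed to converge", call. = FALSE)
  bf10 <- exp(m + log(quad$value))
  structure(list(bf10 = bf10, bf01 = 1 / bf10,
                 direction = direction, kappa = kappa),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  lab <- if (!is.null(x$kappa)) sprintf("stretched beta width %.2f", x$kappa)
         else sprintf("Cauchy scale %.3f", x$rscale)
  side <- if (x$bf10 >= 1)
    sprintf("BF10 = %.3g", x$bf10) else sprintf("BF01 = %.3g", x$bf01)
  cat(sprintf("%s (%s, %s)\n", side, x$direction, lab))
  invisible(x)
}

#' JZS Bayes factor for a t statistic
#'
#' Default-prior Bayes factor for one-sample/paired or two-sample t tests: a
#' Cauchy prior with scale `rscale` on the standardised effect size,
#' integrated against the noncentral-t likelihood of the observed statistic.
#' The medium scale `sqrt(2)/2` is the default.
#'
#' @param t observed t statistic.
#' @param n1 sample size (first group, or the paired/one-sample n).
#' @param n2 second group size, or `NULL` for one-sample/paired designs.
#' @param rscale Cauchy prior scale.
#' @return an object of class `bayes_factor` with `bf10`, `bf01`,
#'   `direction = "two_sided"`, `rscale`.
#' @export
#' @examples
#' bf_ttest(1.10, 26)   # paired design, n = 26
bf_ttest <- function(t, n1, n2 = NULL, rscale = sqrt(2) / 2) {
  .stopifnot_scalar(t, "t"); .stopifnot_scalar(n1, "n1")
  if (n1 < 2) stop("design sizes must be >= 2", call. = FALSE)
  if (is.null(n2)) {
    neff <- n1; df <- n1 - 1
  } else {
    if (n2 < 2) stop("design sizes must be >= 2", call. = FALSE)
    neff <- n1 * n2 / (n1 + n2); df <- n1 + n2 - 2
  }
  # dt(ncp) emits sub-tolerance precision warnings; its accuracy (~1e-8)
  # exceeds the 1e-6 quadrature tolerance used here
  marg1 <- suppressWarnings(integrate(function(delta)
    dt(t, df, ncp = delta * sqrt(neff)) * dcauchy(delta, 0, rscale),
    -Inf, Inf, rel.tol = 1e-6, stop.on.error = FALSE))
  if (marg1$message != "OK" || !is.finite(marg1$value) || marg1$value <= 0)
    stop("Bayes factor quadrature failed to converge", call. = FALSE)
  bf10 <- marg1$value / dt(t, df)
  structure(list(bf10 = bf10, bf01 = 1 / bf10,
                 direction = "two_sided", rscale = rscale),
            class = "bayes_factor")
}

#' Order-effect correction for counterbalanced task order
#'
#' Removes the average difference between task-order groups by subtracting
#' `(mean of the adjusted group - mean of the other group)` from every
#' member of the adjusted group. Group means are equal afterwards and
#' within-group variances are unchanged, so order-related variance cannot
#' masquerade as individual differences.
#'
#' @param scores numeric vector.
#' @param order_group factor/character with exactly two levels.
#' @param adjust which group to shift (default: the first level).
#' @return the corrected numeric vector.
#' @export
#' @examples
#' order_correction(c(10, 10, 12, 12), c("A", "A", "B", "B"))
order_correction <- function(scores, order_group, adjust = NULL) {
  g <- as.factor(order_group)
  if (nlevels(g) != 2)
    stop("order_group must have exactly two levels", call. = FALSE)
  if (is.null(adjust)) adjust <- levels(g)[1]
  if (!adjust %in% levels(g))
    stop("'adjust' is not a level of order_group", call. = FALSE)
  other <- setdiff(levels(g), adjust)
  delta <- mean(scores[g == adjust], na.rm = TRUE) -
    mean(scores[g == other], na.rm = TRUE)
  out <- scores
  out[g == adjust] <- out[g == adjust] - delta
  out
}

#' Association table between DI rate and the other measures
#'
#' Computes, for each requested measure, the Pearson correlation with DI
#' rate on pairwise-complete cases (honouring per-measure exclusion flags
#' `excluded_*` where present) plus a directional Bayes factor under the
#' stretched beta prior, with a robustness column per prior width.
#'
#' @param scores a [score_cohort()] data frame (one session).
#' @param measures named character vector: names are labels, values are
#'   column names in `scores`.
#' @param directions named character vector of BF directions per label
#'   (default `"two_sided"`).
#' @param kappas prior widths for the robustness table.
#' @return a data frame, one row per measure pair.
#' @export
association_table <- function(scores, measures,
                              directions = NULL,
                              kappas = c(0.5, 1.0, 1.5)) {
  rows <- lapply(names(measures), function(lab) {
    col <- measures[[lab]]
    x <- scores$di_rate; y <- scores[[col]]
    drop <- rep(FALSE, nrow(scores))
    if (!is.null(scores$excluded_guess)) drop <- drop | scores$excluded_guess
    if (!is.null(scores$excluded_di_rate)) drop <- drop | scores$excluded_di_rate
    flag <- scores[[paste0("excluded_", col)]]
    if (!is.null(flag)) drop <- drop | flag
    x[drop] <- NA; y[drop] <- NA
    ct <- cor_pearson(x, y)
    dirn <- if (!is.null(directions) && lab %in% names(directions))
      directions[[lab]] else "two_sided"
    bfs <- vapply(kappas, function(k)
      bf_cor(ct$r, ct$n, direction = dirn, kappa = k)$bf10, numeric(1))
    out <- data.frame(measure = lab, r = ct$r, df = ct$df, p = ct$p,
                      direction = dirn, stringsAsFactors = FALSE)
    for (i in seq_along(kappas))
      out[[sprintf("bf10_kappa_%.1f", kappas[i])]] <- bfs[i]
    out
  })
  do.call(rbind, rows)
}
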