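# Internal numerical helpers: Gauss-Hermite expectations over standard-normal
# latents, logit-normal moment matching, and reproducible sub-seed derivation.

# Gauss-Hermite nodes/weights recast for E[f(Z)], Z ~ N(0,1).
.gh <- local({
  cache <- NULL
  function(n = 61L) {
    if (is.null(cache) || length(cache$z) != n) {
      gh <- pracma::gaussHermite(n)
      cache <<- list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
    }
    cache
  }
})

# E[f(Z)] for Z ~ N(0,1)
.e_norm <- function(f, n = 61L) {
  gh <- .gh(n)
  sum(gh$w * f(gh$z))
}

# Mean and SD of plogis(a + b*Z)
.logitnorm_moments <- function(a, b) {
  m1 <- .e_norm(function(z) plogis(a + b * z))
  m2 <- .e_norm(function(z) plogis(a + b * z)^2)
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Solve (a, b >= 0) so that plogis(a + b*Z) has the requested mean and SD.
# Any distribution on (0,1) with mean m has SD < sqrt(m(1-m)); the logit-normal
# family approaches that bound as b -> Inf, so feasibility is checked against it.
.logitnorm_solve <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("propensity mean must lie strictly inside (0, 1)", call. = FALSE)
  if (sd < 0) stop("propensity sd must be >= 0", call. = FALSE)
  if (sd == 0) return(c(a = qlogis(mean), b = 0))
  bound <- sqrt(mean * (1 - mean))
  if (sd >= 0.98 * bound)
    stop(sprintf(
      "infeasible calibration: sd %.3f too large for mean %.3f (bound %.3f)",
      sd, mean, bound), call. = FALSE)
  solve_a <- function(b) {
    uniroot(function(a) .e_norm(function(z) plogis(a + b * z)) - mean,
            lower = -60, upper = 60, tol = 1e-12)$root
  }
  f <- function(b) .logitnorm_moments(solve_a(b), b)[["sd"]] - sd
  b <- uniroot(f, lower = 1e-8, upper = 60, tol = 1e-10)$root
  c(a = solve_a(b), b = b)
}

# Correlation between plogis(a + b*Z) and the latent Z itself.
.logitnorm_cor_theta <- function(a, b) {
  if (b == 0) return(0)
  mo <- .logitnorm_moments(a, b)
  cov <- .e_norm(function(z) z * plogis(a + b * z))
  cov / mo[["sd"]]
}

# Correlation between g1(U) and g2(T) where (U, T) are standard bivariate
# normal with correlation rho; evaluated with a nested Gauss-Hermite grid.
.cor_bvn_transforms <- function(g1, g2, rho, n = 41L) {
  gh <- .gh(n)
  z <- gh$z; w <- gh$w
  # E[g1(U) | T = t] with U = rho*t + sqrt(1-rho^2)*e
  s <- sqrt(max(1 - rho^2, 0))
  cond <- vapply(z, function(t) sum(w * g1(rho * t + s * z)), numeric(1))
  e1 <- sum(w * cond)
  e2 <- sum(w * g2(z))
  e12 <- sum(w * cond * g2(z))
  v1 <- sum(w * vapply(z, function(t) sum(w * g1(rho * t + s * z)^2), numeric(1))) - e1^2
  v2 <- sum(w * g2(z)^2) - e2^2
  (e12 - e1 * e2) / sqrt(max(v1, 1e-300) * max(v2, 1e-300))
}

# Solve the latent loading lambda so that cor(g1(lambda*T + ...), g2(T)) hits
# `target`; g1 applied to a unit-variance latent correlated lambda with T.
.solve_loading <- function(g1, g2, target, interval = c(-0.999, 0.999)) {
  if (target == 0) return(0)
  f <- function(l) .cor_bvn_transforms(g1, g2, l) - target
  lo <- f(interval[1]); hi <- f(interval[2])
  if (sign(lo) == sign(hi))
    stop(sprintf("infeasible calibration: correlation target %.2f out of reach", target),
         call. = FALSE)
  uniroot(f, interval = interval, tol = 1e-8)$root
}

# Centered, unit-SD, right-skewed noise: scaled shifted log-normal.
# sigma_ln controls skewness; the result has mean 0 and SD 1. The default
# gives skewness ~1.5 (clearly right-skewed without the extreme tail that
# would dilute moment calibration in finite samples).
.rskew <- function(n, sigma_ln = 0.45) {
  raw <- exp(sigma_ln * rnorm(n))
  m <- exp(sigma_ln^2 / 2)
  s <- sqrt((exp(sigma_ln^2) - 1) * exp(sigma_ln^2))
  (raw - m) / s
}

# Deterministic 31-bit sub-seed from a master seed and a character tag, so
# independent generator stages draw from unrelated streams.
.derive_seed <- function(seed, tag) {
  h <- sum(as.integer(charToRaw(tag)) * (31^(seq_along(charToRaw(tag)) %% 7)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

.stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
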