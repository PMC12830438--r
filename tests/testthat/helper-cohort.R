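# Shared fixtures: small cohorts and hand-built trial tables, all generated
# in code under fixed seeds.

small_config <- function(n = 40, seed = 101, ...) {
  cohort_config(n_participants = n,
                n_trials = list(di = 40, ab = 40, time = 40, rt = 60),
                seed = seed, ...)
}

# deterministic binary trial matrix with participant-level propensities
propensity_matrix <- function(p, n_trials, seed = 1) {
  set.seed(seed)
  matrix(rbinom(length(p) * n_trials, 1, rep(p, n_trials)),
         nrow = length(p))
}

# independent KR-20 computation (population-variance form; the ratio of item
# to total variance is denominator-invariant, so this must equal alpha)
kr20 <- function(mat) {
  k <- ncol(mat)
  p <- colMeans(mat)
  var_pop <- mean((rowSums(mat) - mean(rowSums(mat)))^2)
  k / (k - 1) * (1 - sum(p * (1 - p)) / var_pop)
}
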