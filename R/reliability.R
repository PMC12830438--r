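# Reliability engines: split-half with Spearman-Brown correction, Cronbach's
# alpha on binary trial items (= KR-20), test-retest correlation, and the
# iterative down-sampling grid over participant and trial counts.

#' Split-half correlation of per-trial scores
#'
#' Splits the trial columns of a participants x trials matrix into two
#' halves, scores each participant as the mean of each half (for binary DI
#' items: the intrusion proportion), and returns the Pearson correlation of
#' the two half-score vectors. The `odd_even` scheme partitions by 0-based
#' trial-index parity (even positions form the first half); `random`
#' partitions the columns at random.
#'
#' @param mat numeric matrix, participants in rows, trials in columns.
#' @param scheme `"odd_even"` (default) or `"random"`.
#' @param seed optional seed used only by the random scheme.
#' @return the raw half-score correlation, or `NA` (with attribute
#'   `undefined = TRUE`) when either half has zero variance.
#' @export
#' @examples
#' m <- matrix(rbinom(200, 1, rep(c(.2, .8), each = 20)), nrow = 10)
#' split_half(m)
split_half <- function(mat, scheme = c("odd_even", "random"), seed = NULL) {
  scheme <- match.arg(scheme)
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) stop("need at least 3 participants", call. = FALSE)
  if (ncol(mat) < 2) stop("need at least 2 trials", call. = FALSE)
  k <- ncol(mat)
  if (scheme == "odd_even") {
    first <- seq(1, k, by = 2)          # 0-based even indices
  } else {
    if (!is.null(seed)) set.seed(seed)
    first <- sample(k, floor(k / 2))
  }
  h1 <- rowMeans(mat[, first, drop = FALSE])
  h2 <- rowMeans(mat[, -first, drop = FALSE])
  if (sd(h1) == 0 || sd(h2) == 0)
    return(structure(NA_real_, undefined = TRUE))
  cor(h1, h2)
}

#' Spearman-Brown prophecy correction
#'
#' Steps a half-length correlation up to full length: `2 r / (1 + r)`.
#' Strictly increasing, and maps \[0, 1\] onto \[0, 1\].
#'
#' @param r_half raw half-score correlation in (-1, 1\].
#' @return the corrected reliability, or `NA` (attribute `undefined`) at
#'   `r_half = -1` where the formula has a pole.
#' @export
#' @examples
#' spearman_brown(0.81818)  # ~= .90
spearman_brown <- function(r_half) {
  out <- ifelse(is.na(r_half) | r_half == -1, NA_real_,
                2 * r_half / (1 + r_half))
  if (anyNA(out)) attr(out, "undefined") <- TRUE
  out
}

#' Cronbach's alpha over trial items
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total score))`,
#' with all variances using the same n-1 denominator. Trials are aligned by
#' within-participant index (column position). For binary items this equals
#' KR-20.
#'
#' @param mat numeric matrix, participants in rows, trial items in columns.
#' @return alpha, or `NA` (attribute `undefined`) when the total-score
#'   variance is zero.
#' @export
cronbach_alpha <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) stop("need at least 3 participants", call. = FALSE)
  if (ncol(mat) < 2) stop("need at least 2 items", call. = FALSE)
  k <- ncol(mat)
  total_var <- var(rowSums(mat))
  if (total_var == 0) return(structure(NA_real_, undefined = TRUE))
  item_var <- sum(apply(mat, 2, var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Full reliability summary for a trial matrix
#'
#' Convenience wrapper: raw split-half correlation, its Spearman-Brown
#' correction, and Cronbach's alpha, bundled with the sample sizes.
#'
#' @inheritParams split_half
#' @return an object of class `reliability_result` with fields `r_half`,
#'   `r_sb`, `alpha`, `n_participants`, `n_trials`, `split_scheme`.
#' @export
trial_reliability <- function(mat, scheme = c("odd_even", "random"),
                              seed = NULL) {
  scheme <- match.arg(scheme)
  r <- split_half(mat, scheme, seed)
  structure(list(
    r_half = as.numeric(r), r_sb = as.numeric(spearman_brown(r)),
    alpha = as.numeric(cronbach_alpha(mat)),
    n_participants = nrow(mat), n_trials = ncol(mat),
    split_scheme = scheme), class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(
    "Reliability (%d participants, %d trials, %s split):\n  r_half = %.3f, Spearman-Brown r' = %.3f, alpha = %.3f\n",
    x$n_participants, x$n_trials, x$split_scheme,
    x$r_half, x$r_sb, x$alpha))
  invisible(x)
}

#' Iterative down-sampling reliability grid
#'
#' For every combination of `n` participants and `t` trials, repeatedly
#' samples `n` rows and `t` columns of the trial matrix uniformly without
#' replacement (sampled trial columns keep their temporal order), computes
#' the Spearman-Brown-corrected odd/even split-half reliability and
#' Cronbach's alpha on the subsample, and averages over iterations with
#' defined results. Undefined iterations (zero-variance subsamples) are
#' dropped from the cell mean, and the per-cell valid counts make that
#' auditable. One master seed deterministically derives an independent
#' stream per cell, so any cell is reproducible on its own.
#'
#' @param mat participants x trials matrix (binary DI indicators).
#' @param n_values,t_values participant and trial counts to scan. Defaults
#'   are 10..100 and 20..80, both in steps of 2 (clipped to the data).
#' @param iterations sampling iterations per cell (default 100).
#' @param seed master seed for the whole grid.
#' @return a long-format data frame of class `downsample_grid` with columns
#'   `n`, `t`, `mean_r_sb`, `mean_alpha`, `valid_r_sb`, `valid_alpha`,
#'   `valid_iterations`; `iterations` and `seed` are attached as attributes.
#' @export
downsample_grid <- function(mat,
                            n_values = seq(10, 100, by = 2),
                            t_values = seq(20, 80, by = 2),
                            iterations = 100, seed = 1L) {
  mat <- as.matrix(mat)
  n_values <- as.integer(n_values); t_values <- as.integer(t_values)
  if (max(n_values) > nrow(mat))
    stop("max(n_values) exceeds available participants", call. = FALSE)
  if (max(t_values) > ncol(mat))
    stop("max(t_values) exceeds available trials", call. = FALSE)
  grid <- expand.grid(n = n_values, t = t_values, KEEP.OUT.ATTRS = FALSE)
  res <- t(mapply(function(n, t) {
    set.seed(.derive_seed(seed, sprintf("cell_%d_%d", n, t)))
    rsb <- alp <- numeric(iterations)
    for (i in seq_len(iterations)) {
      rows <- sample.int(nrow(mat), n)
      cols <- sort(sample.int(ncol(mat), t))
      sub <- mat[rows, cols, drop = FALSE]
      rsb[i] <- spearman_brown(split_half(sub, "odd_even"))
      alp[i] <- cronbach_alpha(sub)
    }
    c(mean_r_sb = mean(rsb, na.rm = TRUE),
      mean_alpha = mean(alp, na.rm = TRUE),
      valid_r_sb = sum(!is.na(rsb)),
      valid_alpha = sum(!is.na(alp)),
      valid_iterations = sum(!is.na(rsb) & !is.na(alp)))
  }, grid$n, grid$t))
  out <- cbind(grid, as.data.frame(res))
  out$mean_r_sb[out$valid_r_sb == 0] <- NA_real_
  out$mean_alpha[out$valid_alpha == 0] <- NA_real_
  structure(out, class = c("downsample_grid", "data.frame"),
            iterations = iterations, seed = seed)
}

#' @export
print.downsample_grid <- function(x, ...) {
  cat(sprintf("Down-sampling reliability grid: %d cells, %d iterations each (seed %d)\n",
              nrow(x), attr(x, "iterations"), attr(x, "seed")))
  NextMethod()
}

#' Test-retest reliability of a score across two sessions
#'
#' Pearson correlation of a per-participant score between two sessions,
#' pairing rows by `participant_id`; participants missing from either
#' session (or flagged `NA`) are dropped.
#'
#' @param scores1,scores2 data frames with `participant_id` and the score
#'   column.
#' @param measure score column name (default `"di_rate"`).
#' @return an object of class `correlation_result` (see [cor_pearson()]).
#' @export
retest_reliability <- function(scores1, scores2, measure = "di_rate") {
  m <- merge(scores1[, c("participant_id", measure)],
             scores2[, c("participant_id", measure)],
             by = "participant_id", suffixes = c("_1", "_2"))
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3)
    stop("fewer than 3 paired participants after exclusions", call. = FALSE)
  cor_pearson(m[[paste0(measure, "_1")]], m[[paste0(measure, "_2")]])
}

#' Binary intrusion matrix from a DI trial table
#'
#' Reshapes one session of DI trials into a participants x trials 0/1 matrix
#' (1 = intrusion), aligned by within-participant trial rank, ready for
#' [split_half()], [cronbach_alpha()] and [downsample_grid()].
#'
#' @param trials a data frame in the `di_trials` schema.
#' @param session which session to extract (default 1).
#' @return an integer matrix with participant ids as row names.
#' @export
di_trial_matrix <- function(trials, session = 1L) {
  if (!is.null(trials$session))
    trials <- trials[trials$session == session, , drop = FALSE]
  if (nrow(trials) == 0) stop("no trials in the requested session", call. = FALSE)
  intr <- as.integer(classify_response(trials$target_id, trials$posttarget_id,
                                       trials$response_id) == "intrusion")
  ord <- order(trials$participant_id, trials$trial_index)
  pid <- trials$participant_id[ord]
  ranks <- ave(seq_along(pid), pid, FUN = seq_along)
  ids <- unique(pid)
  nt <- max(ranks)
  m <- matrix(NA_integer_, length(ids), nt,
              dimnames = list(ids, NULL))
  m[cbind(match(pid, ids), ranks)] <- intr[ord]
  if (anyNA(m))
    stop("unbalanced trial counts across participants", call. = FALSE)
  m
}

#' Split-half reliability of a derived score
#'
#' For measures defined by within-participant contrasts (AB magnitude, RT
#' effects), each half must be scored fully before correlating: the trials
#' of each participant are partitioned by trial-index parity, `score_fun` is
#' applied to each half, and the two half-score vectors are correlated and
#' Spearman-Brown corrected.
#'
#' @param trials trial data frame with `participant_id` and `trial_index`.
#' @param score_fun function taking a trial subset and returning a data
#'   frame with `participant_id` and the score as its second column.
#' @return a list with `r_half` and `r_sb`.
#' @export
split_half_derived <- function(trials, score_fun) {
  even <- trials[trials$trial_index %% 2 == 0, , drop = FALSE]
  odd <- trials[trials$trial_index %% 2 == 1, , drop = FALSE]
  s1 <- score_fun(even); s2 <- score_fun(odd)
  m <- merge(s1, s2, by = "participant_id", suffixes = c("_1", "_2"))
  m <- m[complete.cases(m), , drop = FALSE]
  v1 <- m[[2]]; v2 <- m[[3]]
  if (nrow(m) < 3 || sd(v1) == 0 || sd(v2) == 0)
    return(list(r_half = NA_real_, r_sb = NA_real_))
  r <- cor(v1, v2)
  list(r_half = r, r_sb = as.numeric(spearman_brown(r)))
}
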