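# Trial scoring and exclusion rules: DI response classification, per-
# participant rates, attentional-blink scores, RT preprocessing, and the
# participant-level exclusion flags.

#' Classify a DI-trial response
#'
#' A response equal to the target is `correct`, equal to the post-target
#' distractor is an `intrusion`, and anything else is `other` (a guess).
#' Vectorised over its arguments.
#'
#' @param target_id,posttarget_id,response_id stimulus/response identities.
#'   `target_id` and `posttarget_id` must differ on every trial.
#' @return a character vector in \{"correct", "intrusion", "other"\}.
#' @export
#' @examples
#' classify_response(3, 6, 6)  # "intrusion"
classify_response <- function(target_id, posttarget_id, response_id) {
  if (any(target_id == posttarget_id, na.rm = TRUE))
    stop("invalid trial: target equals post-target distractor", call. = FALSE)
  ifelse(response_id == target_id, "correct",
         ifelse(response_id == posttarget_id, "intrusion", "other"))
}

#' DI and guess rates per participant and session
#'
#' Scores every trial with [classify_response()] and aggregates to one row
#' per participant x session: `di_rate` = intrusions / trials, `guess_rate` =
#' other / trials. Category counts always partition the trials.
#'
#' @param trials a data frame in the `di_trials` schema (a `session` column
#'   is optional and defaults to 1).
#' @return a data frame with columns `participant_id`, `session`,
#'   `n_di_trials`, `di_rate`, `guess_rate`, `accuracy`.
#' @export
#' @examples
#' tr <- data.frame(participant_id = "p1", target_id = 3, posttarget_id = 6,
#'                  response_id = c(3, 6, 6, 8))
#' di_rate(tr)  # di_rate .5, guess_rate .25
di_rate <- function(trials) {
  if (nrow(trials) == 0) stop("no trials to score", call. = FALSE)
  if (is.null(trials$session)) trials$session <- 1L
  cat <- classify_response(trials$target_id, trials$posttarget_id,
                           trials$response_id)
  key <- interaction(trials$participant_id, trials$session, drop = TRUE, sep = "\x1f")
  n <- as.vector(rowsum(rep(1L, nrow(trials)), key))
  ni <- as.vector(rowsum(as.integer(cat == "intrusion"), key))
  no <- as.vector(rowsum(as.integer(cat == "other"), key))
  ids <- do.call(rbind, strsplit(levels(key), "\x1f", fixed = TRUE))
  out <- data.frame(
    participant_id = ids[, 1],
    session = as.integer(ids[, 2]),
    n_di_trials = n,
    di_rate = ni / n,
    guess_rate = no / n,
    accuracy = (n - ni - no) / n,
    stringsAsFactors = FALSE)
  out[order(out$participant_id, out$session), , drop = FALSE]
}

#' Flag participants with high guess rates
#'
#' Participants whose guess rate (reports of neither the target nor the
#' post-target) exceeds the threshold are flagged: their low intrusion rates
#' are uninformative about attention speed. The boundary is strict: a guess
#' rate exactly at the threshold is retained.
#'
#' @param scores a data frame with a `guess_rate` column.
#' @param threshold strict exclusion threshold (default .25).
#' @return `scores` with logical column `excluded_guess` added.
#' @export
flag_high_guess <- function(scores, threshold = 0.25) {
  scores$excluded_guess <- scores$guess_rate > threshold
  scores
}

#' Attentional-blink scores
#'
#' T1 accuracy and T2 accuracy by lag are computed over all two-target trials
#' of each lag (not conditioned on T1 correctness); the AB magnitude is T2
#' accuracy at lag 7 minus lag 3, so a deeper blink gives a larger positive
#' value. A participant with no trials at one of the lags gets `NA` scores
#' and `ab_undefined = TRUE` rather than a 0.
#'
#' @param trials a data frame in the `ab_trials` schema.
#' @param condition_on_t1 if `TRUE`, T2 accuracies are computed only on
#'   trials where T1 was reported correctly (a common convention in
#'   attentional-blink work; the default is unconditional).
#' @return a data frame with one row per participant x session: `t1_acc`,
#'   `t2_acc_lag3`, `t2_acc_lag7`, `ab_magnitude`, `ab_undefined`.
#' @export
ab_scores <- function(trials, condition_on_t1 = FALSE) {
  if (is.null(trials$session)) trials$session <- 1L
  dbl <- trials[trials$trial_type == "double", , drop = FALSE]
  if (nrow(dbl) == 0) stop("no two-target trials to score", call. = FALSE)
  dbl$t1_ok <- as.integer(dbl$t1_response == dbl$t1_id)
  dbl$t2_ok <- as.integer(dbl$t2_response == dbl$t2_id)
  key <- interaction(dbl$participant_id, dbl$session, drop = TRUE, sep = "\x1f")
  agg <- function(v, subset) {
    num <- rowsum(ifelse(subset, v, 0), key)
    den <- rowsum(as.integer(subset), key)
    ifelse(den > 0, num / den, NA_real_)
  }
  t2_base <- if (condition_on_t1) dbl$t1_ok == 1L else rep(TRUE, nrow(dbl))
  t1 <- agg(dbl$t1_ok, rep(TRUE, nrow(dbl)))
  l3 <- agg(dbl$t2_ok, t2_base & dbl$lag == 3L)
  l7 <- agg(dbl$t2_ok, t2_base & dbl$lag == 7L)
  ids <- do.call(rbind, strsplit(levels(key), "\x1f", fixed = TRUE))
  out <- data.frame(
    participant_id = ids[, 1],
    session = as.integer(ids[, 2]),
    t1_acc = as.vector(t1),
    t2_acc_lag3 = as.vector(l3),
    t2_acc_lag7 = as.vector(l7),
    ab_magnitude = as.vector(l7 - l3),
    stringsAsFactors = FALSE)
  out$ab_undefined <- is.na(out$t2_acc_lag3) | is.na(out$t2_acc_lag7)
  out[order(out$participant_id, out$session), , drop = FALSE]
}

#' Preprocess speeded-RT trials and compute condition means and effects
#'
#' Applies, in order: a correctness filter (RT analyses use correct trials
#' only), an absolute window (trials faster than `rt_min` or slower than
#' `rt_max` are excluded; the boundaries themselves are retained), and a
#' single-pass per-participant per-condition trim of trials more than
#' `sd_k` SDs from that participant-condition mean. Returns the cleaned
#' trials, per-condition mean RTs, the derived effects (cueing effect =
#' different-location minus same-location; Simon effect = incompatible minus
#' compatible), and an exclusion ledger.
#'
#' @param trials a data frame in the `rt_trials` schema for a single task.
#' @param rt_min,rt_max absolute window in ms (strict exclusion outside).
#' @param sd_k trim multiplier for the per-condition pass (strict `>`).
#' @return a list of class `rt_preprocess` with elements `trials`, `means`
#'   (participant x condition mean RTs, wide), `effects` (per participant),
#'   and `ledger` (exclusion counts by stage).
#' @export
rt_preprocess <- function(trials, rt_min = 150, rt_max = 1000, sd_k = 3) {
  task <- unique(trials$task)
  if (length(task) > 1)
    stop("rt_preprocess expects trials from a single task", call. = FALSE)
  known <- list(cueing = c("absent", "different", "same"),
                simon = c("compatible", "incompatible"))
  if (length(task) == 1 && task %in% names(known)) {
    bad <- setdiff(unique(trials$condition), known[[task]])
    if (length(bad))
      stop(sprintf("unknown condition label(s) for task '%s': %s",
                   task, paste(bad, collapse = ", ")), call. = FALSE)
  }
  n0 <- nrow(trials)
  tr <- trials[as.logical(trials$correct), , drop = FALSE]
  n_err <- n0 - nrow(tr)
  keep <- tr$rt_ms >= rt_min & tr$rt_ms <= rt_max
  n_window <- sum(!keep)
  tr <- tr[keep, , drop = FALSE]

  key <- interaction(tr$participant_id, tr$condition, drop = TRUE, sep = "\x1f")
  mu <- ave(tr$rt_ms, key, FUN = mean)
  sdv <- ave(tr$rt_ms, key, FUN = function(x) if (length(x) > 1) sd(x) else 0)
  keep2 <- abs(tr$rt_ms - mu) <= sd_k * sdv | sdv == 0
  n_trim <- sum(!keep2)
  tr <- tr[keep2, , drop = FALSE]

  key2 <- interaction(tr$participant_id, tr$condition, drop = TRUE, sep = "\x1f")
  cm <- rowsum(tr$rt_ms, key2) / as.vector(rowsum(rep(1, nrow(tr)), key2))
  ids <- do.call(rbind, strsplit(levels(key2), "\x1f", fixed = TRUE))
  long <- data.frame(participant_id = ids[, 1], condition = ids[, 2],
                     mean_rt = as.vector(cm), stringsAsFactors = FALSE)
  pts <- sort(unique(long$participant_id))
  conds <- sort(unique(long$condition))
  means <- data.frame(participant_id = pts, stringsAsFactors = FALSE)
  for (cc in conds)
    means[[cc]] <- long$mean_rt[match(paste(pts, cc),
                                      paste(long$participant_id, long$condition))]
  means$overall_rt <- vapply(pts, function(p)
    mean(tr$rt_ms[tr$participant_id == p]), numeric(1))

  effects <- data.frame(participant_id = pts, stringsAsFactors = FALSE)
  if (all(c("different", "same") %in% conds))
    effects$cueing_effect_ms <- means$different - means$same
  if (all(c("incompatible", "compatible") %in% conds))
    effects$simon_effect_ms <- means$incompatible - means$compatible

  structure(list(
    trials = tr, means = means, effects = effects,
    ledger = data.frame(
      stage = c("incorrect", "absolute_window", "sd_trim"),
      n_excluded = c(n_err, n_window, n_trim),
      prop_of_input = c(n_err, n_window, n_trim) / n0)),
    class = "rt_preprocess")
}

#' Flag participant-level outliers on a measure
#'
#' Flags participants whose score lies strictly more than `k` SDs from the
#' sample mean, with mean and SD computed over the full sample including the
#' candidate. Flags are per-measure: exclusion applies only to analyses
#' involving that measure.
#'
#' @param scores a data frame.
#' @param measure column name to screen.
#' @param k SD multiplier (default 3; strict `>`).
#' @return `scores` with logical column `excluded_<measure>` added.
#' @export
flag_outlier_participants <- function(scores, measure, k = 3) {
  x <- scores[[measure]]
  if (is.null(x)) stop(sprintf("no column '%s' in scores", measure), call. = FALSE)
  m <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
  flag <- !is.na(x) & abs(x - m) > k * s
  scores[[paste0("excluded_", measure)]] <- flag
  scores
}

#' Score a full simulated or loaded cohort
#'
#' Convenience wrapper running [di_rate()], [ab_scores()],
#' [score_time_trials()] and [rt_preprocess()] over the tables of a cohort
#' and merging the results into one row per participant x session, with
#' guess-rate and outlier flags attached.
#'
#' @param cohort a list with elements `di_trials`, and optionally
#'   `ab_trials`, `time_trials`, `rt_trials` (as built by
#'   [simulate_cohort()] or read from CSV).
#' @param guess_threshold threshold for [flag_high_guess()].
#' @return a `data.frame` of participant scores.
#' @export
score_cohort <- function(cohort, guess_threshold = 0.25) {
  scores <- flag_high_guess(di_rate(cohort$di_trials), guess_threshold)
  scores <- flag_outlier_participants(scores, "di_rate")
  if (!is.null(cohort$ab_trials)) {
    ab <- ab_scores(cohort$ab_trials)
    ab <- flag_outlier_participants(ab, "t1_acc")
    scores <- merge(scores, ab, by = c("participant_id", "session"),
                    all.x = TRUE, sort = TRUE)
  }
  if (!is.null(cohort$time_trials)) {
    tj <- score_time_trials(cohort$time_trials)
    scores <- merge(scores, tj, by = "participant_id", all.x = TRUE, sort = TRUE)
  }
  if (!is.null(cohort$rt_trials)) {
    for (task in unique(cohort$rt_trials$task)) {
      pp <- rt_preprocess(cohort$rt_trials[cohort$rt_trials$task == task, ,
                                           drop = FALSE])
      m <- merge(pp$means, pp$effects, by = "participant_id")
      keep <- c("participant_id", "overall_rt",
                intersect(c("cueing_effect_ms", "simon_effect_ms"), names(m)))
      m <- m[, keep, drop = FALSE]
      names(m)[names(m) == "overall_rt"] <- paste0(task, "_rt")
      m <- flag_outlier_participants(m, paste0(task, "_rt"))
      scores <- merge(scores, m, by = "participant_id", all.x = TRUE, sort = TRUE)
    }
  }
  scores[order(scores$participant_id, scores$session), , drop = FALSE]
}
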