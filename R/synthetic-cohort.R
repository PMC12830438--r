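# Synthetic cohort generator: a single-common-factor latent-trait model of the
# four task families (DI, attentional blink, time judgment, speeded RT), with
# moment-calibrated links so the simulated population reproduces the study
# conditions (DI propensity mean/SD, task means/SDs, and the between-measure
# correlation structure).

#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration object. The defaults encode the study
#' conditions the pipeline is calibrated to: a between-subject intrusion
#' propensity with mean .296 and SD .200; T1 accuracy .829 (SD .148); T2
#' accuracy .811 at lag 7 and .408 at lag 3 (attentional-blink magnitude
#' .403, SD .194); mean time error 22.41 degrees (SD 15.14 between subjects);
#' overall RT 547 ms in the cueing task and 436 ms in the Simon task; and
#' latent correlations of the DI propensity with T1 accuracy (-.68), overall
#' RT (+.25), time error (+.40), AB magnitude (0) and reading scores (0).
#'
#' @param n_participants number of participants.
#' @param n_sessions number of DI-task sessions (propensities are stable
#'   across sessions, so test-retest reliability is driven purely by binomial
#'   trial noise).
#' @param n_trials named list of per-task trial counts
#'   (`di` per session, `ab`, `time`, `rt` per task).
#' @param di_mean,di_sd target population mean and SD of the intrusion
#'   propensity. Must satisfy `di_sd < sqrt(di_mean * (1 - di_mean))`.
#' @param guess_mean mean of the per-participant guess propensity, expressed
#'   as a fraction of the non-intrusion probability mass.
#' @param loadings named numeric vector of target product-moment correlations
#'   between the intrusion propensity and each generated measure. Names:
#'   `t1_acc`, `rt`, `time_error`, `ab`, `reading`.
#' @param t1_mean,t1_sd,t2_lag7_mean,t2_lag7_sd,t2_lag3_mean,t2_lag3_sd
#'   population moments of the AB-task accuracy probabilities.
#' @param ab_sd target between-subject SD of the AB magnitude
#'   (lag-7 minus lag-3 accuracy).
#' @param time_mean,time_sd population moments of the per-participant mean
#'   time error, degrees.
#' @param time_trial_sd within-participant SD of single-trial time errors,
#'   degrees.
#' @param wild_frac fraction of time-judgment trials with a wild response
#'   uniform on the circle (exercises the +/-160 degree filter).
#' @param rt_mean,rt_sd population moments of the per-participant mean RT in
#'   the cueing task, ms.
#' @param rt_trial_sd within-participant SD of single-trial RTs, ms.
#' @param simon_shift difference between Simon-task and cueing-task mean RT,
#'   ms (negative: Simon faster).
#' @param cue_offsets condition offsets for the cueing task relative to the
#'   cue-absent condition, ms (`different`, `same`).
#' @param simon_effect RT cost of response-incompatible Simon trials, ms.
#' @param age_mean,age_sd,age_rt_r age distribution (years) and its
#'   correlation with mean RT (orthogonal to the attention-speed trait).
#' @param seed master seed; every generator stage derives its own stream
#'   from it, so the same seed and config give byte-identical output.
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [gen_profiles()], [simulate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 20, seed = 42)
#' cfg$di_mean
cohort_config <- function(n_participants = 100,
                          n_sessions = 2,
                          n_trials = list(di = 60, ab = 120, time = 100, rt = 200),
                          di_mean = 0.296, di_sd = 0.200,
                          guess_mean = 0.115,
                          loadings = c(t1_acc = -0.68, rt = 0.25,
                                       time_error = 0.40, ab = 0, reading = 0),
                          t1_mean = 0.829, t1_sd = 0.148,
                          t2_lag7_mean = 0.811, t2_lag7_sd = 0.177,
                          t2_lag3_mean = 0.408, t2_lag3_sd = 0.200,
                          ab_sd = 0.194,
                          time_mean = 22.41, time_sd = 15.14,
                          time_trial_sd = 35, wild_frac = 0.02,
                          rt_mean = 547, rt_sd = 56, rt_trial_sd = 100,
                          simon_shift = -111,
                          cue_offsets = c(different = 37, same = -36),
                          simon_effect = 81,
                          age_mean = 34.8, age_sd = 6.9, age_rt_r = 0.30,
                          seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants), n_sessions = as.integer(n_sessions),
    n_trials = n_trials, di_mean = di_mean, di_sd = di_sd,
    guess_mean = guess_mean, loadings = loadings,
    t1_mean = t1_mean, t1_sd = t1_sd,
    t2_lag7_mean = t2_lag7_mean, t2_lag7_sd = t2_lag7_sd,
    t2_lag3_mean = t2_lag3_mean, t2_lag3_sd = t2_lag3_sd, ab_sd = ab_sd,
    time_mean = time_mean, time_sd = time_sd,
    time_trial_sd = time_trial_sd, wild_frac = wild_frac,
    rt_mean = rt_mean, rt_sd = rt_sd, rt_trial_sd = rt_trial_sd,
    simon_shift = simon_shift, cue_offsets = cue_offsets,
    simon_effect = simon_effect,
    age_mean = age_mean, age_sd = age_sd, age_rt_r = age_rt_r,
    seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @param config a `cohort_config` list to validate.
#' @export
validate_cohort_config <- function(config) {
  with(config, {
    if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
    if (n_sessions < 1) stop("n_sessions must be >= 1", call. = FALSE)
    if (di_mean <= 0 || di_mean >= 1)
      stop("di_mean must lie in (0, 1)", call. = FALSE)
    if (di_sd < 0) stop("di_sd must be >= 0", call. = FALSE)
    if (di_sd > 0 && di_sd >= sqrt(di_mean * (1 - di_mean)))
      stop(sprintf(
        "infeasible calibration: di_sd = %.3f exceeds the bound sqrt(m(1-m)) = %.3f for di_mean = %.3f",
        di_sd, sqrt(di_mean * (1 - di_mean)), di_mean), call. = FALSE)
    if (wild_frac < 0 || wild_frac > 1)
      stop("wild_frac must lie in [0, 1]", call. = FALSE)
    if (rt_mean <= 0) stop("rt_mean must be positive", call. = FALSE)
    for (nm in c("t1_acc", "rt", "time_error", "ab", "reading"))
      if (is.na(loadings[nm]))
        stop(sprintf("loadings must contain '%s'", nm), call. = FALSE)
  })
  invisible(config)
}

# Solve all link parameters implied by a config. Deterministic (quadrature
# only); cached on the config via attribute when reused through gen_profiles.
.calibrate_links <- function(cfg) {
  di <- .logitnorm_solve(cfg$di_mean, cfg$di_sd)
  g0 <- function(z) plogis(di[["a"]] + di[["b"]] * z)
  c0 <- if (cfg$di_sd > 0) .logitnorm_cor_theta(di[["a"]], di[["b"]]) else 1

  t1 <- .logitnorm_solve(cfg$t1_mean, cfg$t1_sd)
  g1 <- function(u) plogis(t1[["a"]] + t1[["b"]] * u)
  lam_t1 <- if (cfg$di_sd > 0)
    .solve_loading(g1, g0, cfg$loadings[["t1_acc"]]) else 0

  t27 <- .logitnorm_solve(cfg$t2_lag7_mean, cfg$t2_lag7_sd)
  t23 <- .logitnorm_solve(cfg$t2_lag3_mean, cfg$t2_lag3_sd)
  # shared encoding-speed factor between the two lag accuracies (orthogonal to
  # the attention-speed trait when the ab loading is 0): latent correlation
  # chosen so the SD of (lag7 - lag3) matches the target.
  g7 <- function(u) plogis(t27[["a"]] + t27[["b"]] * u)
  g3 <- function(u) plogis(t23[["a"]] + t23[["b"]] * u)
  sd_ab <- function(rho) {
    r <- .cor_bvn_transforms(g7, g3, rho)
    sqrt(cfg$t2_lag7_sd^2 + cfg$t2_lag3_sd^2 -
           2 * r * cfg$t2_lag7_sd * cfg$t2_lag3_sd)
  }
  rho_lat <- if (sd_ab(0) <= cfg$ab_sd) 0 else
    uniroot(function(r) sd_ab(r) - cfg$ab_sd, c(0, 0.999), tol = 1e-7)$root

  # affine-in-theta measures: slope = r * sd / cor(p, theta)
  b_te <- cfg$loadings[["time_error"]] * cfg$time_sd / c0
  if (abs(b_te) >= cfg$time_sd)
    stop("infeasible calibration: time_error loading out of reach", call. = FALSE)
  b_rt <- cfg$loadings[["rt"]] * cfg$rt_sd / c0
  b_age <- cfg$age_rt_r * cfg$rt_sd
  resid_rt <- cfg$rt_sd^2 - b_rt^2 - b_age^2
  if (resid_rt < 0)
    stop("infeasible calibration: rt loadings out of reach", call. = FALSE)

  list(di = di, c0 = c0, t1 = t1, lam_t1 = lam_t1,
       t27 = t27, t23 = t23, rho_lat = rho_lat,
       b_te = b_te, sd_te = sqrt(cfg$time_sd^2 - b_te^2),
       b_rt = b_rt, b_age = b_age, sd_rt = sqrt(resid_rt))
}

#' Generate latent participant profiles
#'
#' Draws one latent attention-speed trait per participant (standard normal;
#' higher = slower attention) and maps it to per-participant generative truths
#' for every task: DI response-category probabilities through a moment-
#' calibrated inverse-logit link, AB-task accuracy probabilities, mean time
#' error, mean RT, age and reading scores. Loadings are solved numerically so
#' the population correlations with the intrusion propensity hit the
#' configured targets.
#'
#' @param config a [cohort_config()] object.
#' @return a data frame of class `latent_profiles`, one row per participant,
#'   with columns `participant_id`, `theta`, `p_correct`, `p_intrusion`,
#'   `p_other`, `t1_acc_true`, `t2_lag3_true`, `t2_lag7_true`,
#'   `mu_time_error`, `mu_rt`, `age`, `reading_swe`, `reading_pde`.
#'   The config and solved link parameters are attached as attributes.
#' @export
#' @examples
#' pr <- gen_profiles(cohort_config(n_participants = 10, seed = 7))
#' stopifnot(all(abs(pr$p_correct + pr$p_intrusion + pr$p_other - 1) < 1e-12))
gen_profiles <- function(config) {
  validate_cohort_config(config)
  links <- .calibrate_links(config)
  n <- config$n_participants
  set.seed(.derive_seed(config$seed, "profiles"))

  theta <- rnorm(n)
  p_int <- plogis(links$di[["a"]] + links$di[["b"]] * theta)
  # guess propensity: beta-distributed fraction of the non-intrusion mass
  gm <- config$guess_mean
  g <- stats::rbeta(n, 20 * gm, 20 * (1 - gm))
  p_other <- g * (1 - p_int)
  p_correct <- 1 - p_int - p_other

  u1 <- links$lam_t1 * theta + sqrt(1 - links$lam_t1^2) * rnorm(n)
  t1_acc <- plogis(links$t1[["a"]] + links$t1[["b"]] * u1)
  eta <- rnorm(n)                       # shared encoding-speed factor
  s <- sqrt(links$rho_lat)
  v7 <- s * eta + sqrt(1 - links$rho_lat) * rnorm(n)
  v3 <- s * eta + sqrt(1 - links$rho_lat) * rnorm(n)
  t2_lag7 <- plogis(links$t27[["a"]] + links$t27[["b"]] * v7)
  t2_lag3 <- plogis(links$t23[["a"]] + links$t23[["b"]] * v3)

  mu_te <- config$time_mean + links$b_te * theta + links$sd_te * .rskew(n)
  age_z <- rnorm(n)
  mu_rt <- config$rt_mean + links$b_rt * theta + links$b_age * age_z +
    links$sd_rt * .rskew(n)
  mu_rt <- pmax(mu_rt, 150)
  age <- round(pmin(pmax(config$age_mean + config$age_sd * age_z, 18), 70))

  w1 <- rnorm(n); w2 <- rnorm(n)
  swe <- round(95 + 12 * w1)
  pde <- round(55 + 11 * (0.53 * w1 + sqrt(1 - 0.53^2) * w2))

  out <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    theta = theta,
    p_correct = p_correct, p_intrusion = p_int, p_other = p_other,
    t1_acc_true = t1_acc, t2_lag3_true = t2_lag3, t2_lag7_true = t2_lag7,
    mu_time_error = mu_te, mu_rt = mu_rt,
    age = age, reading_swe = swe, reading_pde = pde,
    stringsAsFactors = FALSE)
  structure(out, class = c("latent_profiles", "data.frame"),
            config = config, links = links)
}

.profile_config <- function(profiles) {
  cfg <- attr(profiles, "config")
  if (is.null(cfg)) cfg <- cohort_config()
  cfg
}

# sample, for each row, one digit from 2..9 excluding up to two values
.sample_digit_excluding <- function(n, excl1, excl2 = NULL) {
  if (is.null(excl2)) {
    cand <- sample.int(7L, n, replace = TRUE) + 1L   # 2..8
    cand + (cand >= excl1)
  } else {
    lo <- pmin(excl1, excl2); hi <- pmax(excl1, excl2)
    cand <- sample.int(6L, n, replace = TRUE) + 1L   # 2..7
    cand <- cand + (cand >= lo)
    cand + (cand >= hi)
  }
}

#' Generate single-target DI trials
#'
#' Each trial carries a target digit (2-9), a distinct post-target distractor
#' digit, and a response drawn from \{target, post-target, other digit\} with
#' the profile's category probabilities. Trials are exchangeable given the
#' profile: there is no serial structure.
#'
#' @param profiles a [gen_profiles()] data frame.
#' @param n_trials trials per participant (>= 1).
#' @param session session index recorded in the table.
#' @param seed integer seed for this stage.
#' @return a data frame in the `di_trials` schema (see [trial_schemas()]).
#' @export
gen_di_trials <- function(profiles, n_trials, session = 1L, seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  n <- nrow(profiles); nt <- as.integer(n_trials)
  set.seed(.derive_seed(seed, paste0("di", session)))
  N <- n * nt
  idx <- rep(seq_len(n), each = nt)
  target <- sample.int(8L, N, replace = TRUE) + 1L
  post <- .sample_digit_excluding(N, target)
  u <- runif(N)
  pc <- profiles$p_correct[idx]; pi_ <- profiles$p_intrusion[idx]
  category <- ifelse(u < pc, 1L, ifelse(u < pc + pi_, 2L, 3L))
  other <- .sample_digit_excluding(N, target, post)
  response <- ifelse(category == 1L, target, ifelse(category == 2L, post, other))
  data.frame(
    participant_id = profiles$participant_id[idx],
    session = as.integer(session),
    trial_index = rep(seq_len(nt) - 1L, times = n),
    target_id = target, posttarget_id = post, response_id = response,
    stringsAsFactors = FALSE)
}

#' Generate attentional-blink task trials
#'
#' Half the trials are single-target (DI-capable, identical in structure to
#' [gen_di_trials()]); half are two-target, split randomly between lag 3 and
#' lag 7. T1 and T2 correctness are drawn from the profile's accuracy
#' probabilities; T2 fields are present only on two-target trials.
#'
#' @inheritParams gen_di_trials
#' @return a data frame in the `ab_trials` schema.
#' @export
gen_ab_trials <- function(profiles, n_trials, session = 1L, seed = 1L) {
  nt <- as.integer(n_trials)
  if (nt < 2L || nt %% 2L != 0L)
    stop("n_trials must be an even count: the design is half single-, half two-target trials",
         call. = FALSE)
  n <- nrow(profiles)
  set.seed(.derive_seed(seed, paste0("ab", session)))
  N <- n * nt
  idx <- rep(seq_len(n), each = nt)
  # random order of an exactly half/half type split within each participant
  type_block <- rep(c("single", "double"), each = nt / 2L)
  trial_type <- as.vector(vapply(seq_len(n), function(i) sample(type_block),
                                 character(nt)))
  single <- trial_type == "single"

  target <- posttarget <- response <- rep(NA_integer_, N)
  ns <- sum(single)
  target[single] <- sample.int(8L, ns, replace = TRUE) + 1L
  posttarget[single] <- .sample_digit_excluding(ns, target[single])
  u <- runif(ns)
  pc <- profiles$p_correct[idx][single]; pi_ <- profiles$p_intrusion[idx][single]
  cat_s <- ifelse(u < pc, 1L, ifelse(u < pc + pi_, 2L, 3L))
  oth <- .sample_digit_excluding(ns, target[single], posttarget[single])
  response[single] <- ifelse(cat_s == 1L, target[single],
                             ifelse(cat_s == 2L, posttarget[single], oth))

  dbl <- !single
  nd <- sum(dbl)
  lag <- rep(NA_integer_, N)
  lag[dbl] <- ifelse(runif(nd) < 0.5, 3L, 7L)
  t1_id <- t1_resp <- t2_id <- t2_resp <- rep(NA_integer_, N)
  t1_id[dbl] <- sample.int(8L, nd, replace = TRUE) + 1L
  t2_id[dbl] <- .sample_digit_excluding(nd, t1_id[dbl])
  t1_ok <- runif(nd) < profiles$t1_acc_true[idx][dbl]
  p_t2 <- ifelse(lag[dbl] == 7L, profiles$t2_lag7_true[idx][dbl],
                 profiles$t2_lag3_true[idx][dbl])
  t2_ok <- runif(nd) < p_t2
  t1_resp[dbl] <- ifelse(t1_ok, t1_id[dbl],
                         .sample_digit_excluding(nd, t1_id[dbl]))
  t2_resp[dbl] <- ifelse(t2_ok, t2_id[dbl],
                         .sample_digit_excluding(nd, t2_id[dbl]))

  data.frame(
    participant_id = profiles$participant_id[idx],
    session = as.integer(session),
    trial_index = rep(seq_len(nt) - 1L, times = n),
    trial_type = trial_type, lag = lag,
    t1_id = t1_id, t1_response = t1_resp,
    t2_id = t2_id, t2_response = t2_resp,
    target_id = target, posttarget_id = posttarget, response_id = response,
    stringsAsFactors = FALSE)
}

#' Generate clock time-judgment trials
#'
#' Cue angles are uniform on \[0, 360); the response angle is the cue angle
#' plus a signed error drawn from a right-skewed distribution centred on the
#' profile's mean time error, with a configurable small fraction of wild
#' responses uniform on the circle.
#'
#' @inheritParams gen_di_trials
#' @return a data frame in the `time_trials` schema.
#' @export
gen_time_trials <- function(profiles, n_trials, seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  cfg <- .profile_config(profiles)
  n <- nrow(profiles); nt <- as.integer(n_trials)
  set.seed(.derive_seed(seed, "time"))
  N <- n * nt
  idx <- rep(seq_len(n), each = nt)
  cue <- runif(N, 0, 360)
  # mild trial-level skew: a heavier tail would wrap past +/-180 and bias
  # the recovered mean error
  err <- profiles$mu_time_error[idx] + cfg$time_trial_sd * .rskew(N, 0.35)
  wild <- runif(N) < cfg$wild_frac
  err[wild] <- runif(sum(wild), -180, 180)
  data.frame(
    participant_id = profiles$participant_id[idx],
    trial_index = rep(seq_len(nt) - 1L, times = n),
    cue_angle_deg = cue,
    response_angle_deg = (cue + err) %% 360,
    stringsAsFactors = FALSE)
}

# per-task condition tables: sampling probability, RT offset centred so the
# participant's task mean equals mu_rt (+ task shift), and accuracy
.rt_conditions <- function(task, cfg) {
  if (task == "cueing") {
    off <- c(absent = 0, different = cfg$cue_offsets[["different"]],
             same = cfg$cue_offsets[["same"]])
    prob <- c(absent = 0.20, different = 0.64, same = 0.16)
    acc <- c(absent = 0.975, different = 0.950, same = 0.978)
    shift <- 0
  } else if (task == "simon") {
    off <- c(compatible = 0, incompatible = cfg$simon_effect)
    prob <- c(compatible = 0.75, incompatible = 0.25)
    acc <- c(compatible = 0.989, incompatible = 0.857)
    shift <- cfg$simon_shift
  } else stop(sprintf("unknown task '%s'", task), call. = FALSE)
  list(offsets = off - sum(off * prob), prob = prob, acc = acc, shift = shift)
}

#' Generate speeded RT-task trials (cueing or Simon)
#'
#' Per-trial RT is the profile's mean RT plus a task shift, a condition
#' offset and right-skewed trial noise; accuracy is Bernoulli per condition.
#' Condition frequencies follow the task designs (cue present on 80% of
#' cueing-task trials with the cue at the target location on a quarter of
#' those; Simon trials 75% response-compatible).
#'
#' @inheritParams gen_di_trials
#' @param task `"cueing"` or `"simon"`.
#' @return a data frame in the `rt_trials` schema.
#' @export
gen_rt_trials <- function(profiles, task = c("cueing", "simon"),
                          n_trials, seed = 1L) {
  task <- match.arg(task)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  cfg <- .profile_config(profiles)
  cond <- .rt_conditions(task, cfg)
  n <- nrow(profiles); nt <- as.integer(n_trials)
  set.seed(.derive_seed(seed, paste0("rt_", task)))
  N <- n * nt
  idx <- rep(seq_len(n), each = nt)
  ci <- sample(seq_along(cond$prob), N, replace = TRUE, prob = cond$prob)
  condition <- names(cond$prob)[ci]
  rt <- profiles$mu_rt[idx] + cond$shift + cond$offsets[ci] +
    cfg$rt_trial_sd * .rskew(N)
  data.frame(
    participant_id = profiles$participant_id[idx],
    task = task, condition = condition,
    trial_index = rep(seq_len(nt) - 1L, times = n),
    rt_ms = pmax(rt, 1),
    correct = runif(N) < cond$acc[ci],
    stringsAsFactors = FALSE)
}

#' Simulate a full cohort across all four task families
#'
#' Runs [gen_profiles()] and every trial generator with sub-seeds derived
#' from the config's master seed. DI trials are generated for each session
#' with the same stable latent propensities, so the emergent test-retest
#' correlation of observed DI rates reflects only binomial trial noise.
#'
#' @param config a [cohort_config()] object.
#' @return a list of class `di_cohort` with elements `profiles`,
#'   `covariates`, `di_trials`, `ab_trials`, `time_trials`, `rt_trials`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_participants = 12, seed = 3))
#' names(coh)
simulate_cohort <- function(config = cohort_config()) {
  profiles <- gen_profiles(config)
  nt <- config$n_trials
  di <- do.call(rbind, lapply(seq_len(config$n_sessions), function(s)
    gen_di_trials(profiles, nt$di, session = s,
                  seed = .derive_seed(config$seed, "di_task"))))
  ab <- gen_ab_trials(profiles, nt$ab, session = 1L,
                      seed = .derive_seed(config$seed, "ab_task"))
  tm <- gen_time_trials(profiles, nt$time,
                        seed = .derive_seed(config$seed, "time_task"))
  rt <- rbind(
    gen_rt_trials(profiles, "cueing", nt$rt,
                  seed = .derive_seed(config$seed, "rt_task")),
    gen_rt_trials(profiles, "simon", nt$rt,
                  seed = .derive_seed(config$seed, "rt_task")))
  set.seed(.derive_seed(config$seed, "covariates"))
  covariates <- data.frame(
    participant_id = profiles$participant_id,
    age = profiles$age,
    order_group = sample(c("A", "B"), nrow(profiles), replace = TRUE),
    reading_swe = profiles$reading_swe,
    reading_pde = profiles$reading_pde,
    stringsAsFactors = FALSE)
  structure(list(profiles = profiles, covariates = covariates,
                 di_trials = di, ab_trials = ab,
                 time_trials = tm, rt_trials = rt),
            class = "di_cohort", config = config)
}

#' @export
print.di_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Synthetic DI cohort:", cfg$n_participants, "participants,",
      cfg$n_sessions, "DI session(s)\n")
  cat(sprintf("  trials/participant: di %d, ab %d, time %d, rt %d per task\n",
              cfg$n_trials$di, cfg$n_trials$ab, cfg$n_trials$time, cfg$n_trials$rt))
  invisible(x)
}
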