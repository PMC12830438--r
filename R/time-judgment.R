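# Circular time-judgment error pipeline: signed angular error, the +/-160
# degree discard, the per-participant 3-SD trim, and degree <-> millisecond
# conversion at one clock rotation per second.

#' Signed circular error between cued and reported clock angles
#'
#' Returns the reported angle minus the cued angle, wrapped to the signed
#' interval (-180, 180]. Positive errors are clockwise-late reports. Inputs
#' are reduced modulo 360 first; the 180-degree boundary maps to +180 so
#' every error has a unique representative.
#'
#' @param t_c cued clock angle(s), degrees.
#' @param t_p participant-reported angle(s), degrees.
#' @return signed error(s) in (-180, 180].
#' @export
#' @examples
#' circular_error(80, 140)  # +60: a late report
#' circular_error(350, 10)  # +20: wrap-around
circular_error <- function(t_c, t_p) {
  if (any(!is.finite(t_c)) || any(!is.finite(t_p)))
    stop("angles must be finite", call. = FALSE)
  e <- (t_p - t_c) %% 360
  ifelse(e > 180, e - 360, e)
}

#' Convert a time error from degrees to milliseconds
#'
#' The clock hand completes one rotation per `rotation_s` seconds, so an
#' error of `deg` degrees corresponds to `deg / 360 * rotation_s * 1000` ms.
#'
#' @param deg signed error(s), degrees.
#' @param rotation_s rotation period, seconds (default 1).
#' @return signed error(s), milliseconds (full precision; round for display).
#' @export
#' @examples
#' deg_to_ms(22.41)      # 62.25 ms
#' round(deg_to_ms(60))  # 167 ms
deg_to_ms <- function(deg, rotation_s = 1) deg / 360 * rotation_s * 1000

#' Clock-hand step per display frame
#'
#' At a refresh rate of `refresh_hz` and one rotation per `rotation_s`
#' seconds the hand advances `360 / (refresh_hz * rotation_s)` degrees per
#' frame (6 degrees per frame at 60 Hz).
#'
#' @param refresh_hz display refresh rate, Hz.
#' @param rotation_s rotation period, seconds.
#' @return degrees per frame.
#' @export
deg_per_frame <- function(refresh_hz = 60, rotation_s = 1)
  360 / (refresh_hz * rotation_s)

#' Filter time errors: the +/-160 degree discard and per-participant 3-SD trim
#'
#' Stage 1 discards errors equal to or more extreme than 160 degrees (an
#' error near 180 is ambiguous between +500 and -500 ms). Stage 2 applies a
#' single-pass trim of errors strictly more than `sd_k` SDs from that
#' participant's mean of the stage-1 survivors (mean and SD include the
#' candidate). A participant with no retained trials is flagged, not scored 0.
#'
#' @param errors data frame with columns `participant_id` and `error_deg`
#'   (as produced by [circular_error()]), or a bare numeric vector (treated
#'   as a single participant).
#' @param cutoff_deg stage-1 discard boundary, inclusive (default 160).
#' @param sd_k stage-2 trim multiplier (default 3; strict `>`).
#' @return a list of class `time_filter`: `retained` (data frame),
#'   `ledger` (per-stage counts), `undefined_participants` (ids with nothing
#'   left).
#' @export
filter_time_errors <- function(errors, cutoff_deg = 160, sd_k = 3) {
  if (is.numeric(errors))
    errors <- data.frame(participant_id = "p1", error_deg = errors,
                         stringsAsFactors = FALSE)
  n0 <- nrow(errors)
  keep1 <- abs(errors$error_deg) < cutoff_deg
  st1 <- errors[keep1, , drop = FALSE]
  m <- ave(st1$error_deg, st1$participant_id, FUN = mean)
  s <- ave(st1$error_deg, st1$participant_id,
           FUN = function(x) if (length(x) > 1) sd(x) else 0)
  keep2 <- abs(st1$error_deg - m) <= sd_k * s | s == 0
  retained <- st1[keep2, , drop = FALSE]
  undef <- setdiff(unique(errors$participant_id),
                   unique(retained$participant_id))
  structure(list(
    retained = retained,
    ledger = data.frame(
      stage = c("circular_ambiguity", "sd_trim", "retained"),
      n = c(sum(!keep1), sum(!keep2), nrow(retained))),
    undefined_participants = undef,
    n_input = n0), class = "time_filter")
}

#' Mean time error in degrees and milliseconds
#'
#' Arithmetic mean of retained signed errors (the +/-160 discard makes the
#' wrap ambiguity negligible, so the plain mean is used rather than the
#' circular mean), plus its millisecond conversion.
#'
#' @param errors numeric vector of retained signed errors, degrees.
#' @param rotation_s clock rotation period, seconds.
#' @return a list with `mean_deg` and `mean_ms` (full precision).
#' @export
#' @examples
#' mean_time_error(c(20, 25))$mean_ms  # 62.5
mean_time_error <- function(errors, rotation_s = 1) {
  if (length(errors) == 0) stop("no retained errors", call. = FALSE)
  m <- mean(errors)
  list(mean_deg = m, mean_ms = deg_to_ms(m, rotation_s))
}

#' Score a time-judgment trial table
#'
#' Full pipeline from raw angles to per-participant mean time error:
#' [circular_error()] per trial, [filter_time_errors()], then the mean of
#' the retained errors per participant. Participants whose trials were all
#' discarded get `NA` with `time_undefined = TRUE`.
#'
#' @param trials a data frame in the `time_trials` schema.
#' @inheritParams filter_time_errors
#' @return a data frame with `participant_id`, `mean_time_error_deg`,
#'   `mean_time_error_ms`, `n_time_retained`, `time_undefined`.
#' @export
score_time_trials <- function(trials, cutoff_deg = 160, sd_k = 3) {
  err <- data.frame(
    participant_id = trials$participant_id,
    error_deg = circular_error(trials$cue_angle_deg, trials$response_angle_deg),
    stringsAsFactors = FALSE)
  flt <- filter_time_errors(err, cutoff_deg, sd_k)
  ids <- sort(unique(trials$participant_id))
  mdeg <- vapply(ids, function(p) {
    e <- flt$retained$error_deg[flt$retained$participant_id == p]
    if (length(e)) mean(e) else NA_real_
  }, numeric(1))
  nret <- vapply(ids, function(p)
    sum(flt$retained$participant_id == p), integer(1))
  data.frame(
    participant_id = ids,
    mean_time_error_deg = mdeg,
    mean_time_error_ms = deg_to_ms(mdeg),
    n_time_retained = nret,
    time_undefined = ids %in% flt$undefined_participants,
    row.names = NULL, stringsAsFactors = FALSE)
}
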