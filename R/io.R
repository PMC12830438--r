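# Table schemas, CSV reading/writing with validation.
#
# Conventions, enforced by validation: 0-based trial_index, unique within
# participant x session x task; angles in the half-open interval [0, 360);
# RTs in milliseconds as floating point, strictly positive.

.schemas <- list(
  di_trials = list(
    required = c("participant_id", "session", "trial_index",
                 "target_id", "posttarget_id", "response_id"),
    integer = c("session", "trial_index", "target_id", "posttarget_id",
                "response_id"),
    key = c("participant_id", "session", "trial_index")),
  ab_trials = list(
    required = c("participant_id", "session", "trial_index", "trial_type",
                 "lag", "t1_id", "t1_response", "t2_id", "t2_response",
                 "target_id", "posttarget_id", "response_id"),
    integer = c("session", "trial_index", "lag", "t1_id", "t1_response",
                "t2_id", "t2_response", "target_id", "posttarget_id",
                "response_id"),
    key = c("participant_id", "session", "trial_index")),
  time_trials = list(
    required = c("participant_id", "trial_index", "cue_angle_deg",
                 "response_angle_deg"),
    integer = c("trial_index"),
    key = c("participant_id", "trial_index")),
  rt_trials = list(
    required = c("participant_id", "task", "condition", "trial_index",
                 "rt_ms", "correct"),
    integer = c("trial_index"),
    key = c("participant_id", "task", "trial_index")),
  covariates = list(
    required = c("participant_id", "age", "order_group",
                 "reading_swe", "reading_pde"),
    integer = character(0),
    key = c("participant_id"),
    soft = c("age", "reading_swe", "reading_pde")))

#' Trial-table schemas
#'
#' The five delimiter-separated table layouts the pipeline consumes and
#' emits: `di_trials`, `ab_trials`, `time_trials`, `rt_trials`,
#' `covariates`. Each schema lists its required columns, integer-typed
#' columns, and the key whose combinations must be unique.
#'
#' @return a named list of schema definitions.
#' @export
trial_schemas <- function() .schemas

#' Validate a table against a schema
#'
#' Type-coerces and checks the schema's invariants: required columns
#' present, non-empty participant ids, unique key combinations, angles in
#' \[0, 360), positive RTs, lag in \{3, 7\} on two-target rows. Hard
#' violations abort with the offending row numbers; missing values in soft
#' (covariate) columns only warn.
#'
#' @param df a data frame.
#' @param schema a schema name from [trial_schemas()].
#' @return the validated (type-coerced) data frame, invisibly classed.
#' @export
validate_table <- function(df, schema) {
  sc <- .schemas[[schema]]
  if (is.null(sc)) stop(sprintf("unknown schema '%s'", schema), call. = FALSE)
  missing_cols <- setdiff(sc$required, names(df))
  if (length(missing_cols))
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  bad_rows <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop(sprintf("%s (rows %s)", what,
                   paste(head(rows, 10), collapse = ", ")), call. = FALSE)
  }
  df$participant_id <- as.character(df$participant_id)
  bad_rows(is.na(df$participant_id) | df$participant_id == "",
           "empty participant_id")
  for (col in sc$integer) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad_rows(!is.na(df[[col]]) & is.na(v), sprintf("non-integer '%s'", col))
    df[[col]] <- v
  }
  key <- do.call(paste, c(df[sc$key], sep = "\x1f"))
  bad_rows(duplicated(key),
           sprintf("duplicate key (%s)", paste(sc$key, collapse = ", ")))
  if (schema == "time_trials") {
    for (col in c("cue_angle_deg", "response_angle_deg")) {
      df[[col]] <- as.numeric(df[[col]])
      bad_rows(!is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] >= 360,
               sprintf("'%s' outside [0, 360)", col))
    }
  }
  if (schema == "rt_trials") {
    df$rt_ms <- as.numeric(df$rt_ms)
    bad_rows(!is.finite(df$rt_ms) | df$rt_ms <= 0, "rt_ms not positive")
    df$correct <- as.logical(df$correct)
    bad_rows(is.na(df$correct), "'correct' not logical")
  }
  if (schema == "ab_trials") {
    dbl <- !is.na(df$trial_type) & df$trial_type == "double"
    bad_rows(dbl & (is.na(df$lag) | !df$lag %in% c(3L, 7L)),
             "lag must be 3 or 7 on two-target rows")
  }
  if (!is.null(sc$soft)) {
    for (col in sc$soft)
      if (anyNA(df[[col]]))
        warning(sprintf("missing values in soft column '%s'", col),
                call. = FALSE)
  }
  invisible(df)
  df
}

#' Read and validate a trial table from CSV
#'
#' @param path path to a delimiter-separated file with header.
#' @param schema schema name from [trial_schemas()].
#' @return the validated data frame.
#' @export
read_trial_table <- function(path, schema) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  validate_table(read.csv(path, stringsAsFactors = FALSE), schema)
}

#' Write a trial table to CSV (validating first)
#'
#' @param df a data frame conforming to the schema.
#' @param path output path.
#' @param schema schema name; validated before writing.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(df, path, schema) {
  df <- validate_table(df, schema)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
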