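TRIAL_COLUMNS <- c("session_id", "trial_index", "condition_window",
                   "condition_level", "q_A", "q_B", "order", "side_A",
                   "forced", "stim_on", "choice", "error_code", "rt_ms")

canonicalize_trials <- function(df) {
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing))
    abort_stimchoice(paste("missing mandatory column(s):",
                           paste(missing, collapse = ", ")),
                     "stimchoice_schema_error")
  df$session_id <- as.character(df$session_id)
  df$trial_index <- as.integer(df$trial_index)
  df$condition_window <- as.character(df$condition_window)
  df$condition_level <- as.character(df$condition_level)
  df$q_A <- as.integer(df$q_A)
  df$q_B <- as.integer(df$q_B)
  df$order <- as.character(df$order)
  df$side_A <- as.character(df$side_A)
  df$forced <- as.integer(df$forced)
  df$stim_on <- as.integer(df$stim_on)
  df$choice <- as.character(df$choice)
  df$error_code <- as.character(df$error_code)
  # canonical times are milliseconds at 1 us resolution, so the text
  # round trip is exact
  df$rt_ms <- round(as.numeric(df$rt_ms), 3)
  extra <- setdiff(names(df), TRIAL_COLUMNS)
  df[, c(TRIAL_COLUMNS, extra), drop = FALSE]
}

validate_trials <- function(df) {
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing))
    abort_stimchoice(paste("missing mandatory column(s):",
                           paste(missing, collapse = ", ")),
                     "stimchoice_schema_error")
  nf <- df$forced == 0L
  qa <- df$q_A[nf]; qb <- df$q_B[nf]
  if (any(!is.finite(qa)) || any(!is.finite(qb)) ||
      any(qa != round(qa)) || any(qb != round(qb)) || any(qa < 1) || any(qb < 1))
    abort_stimchoice("non-integer or non-positive quantities on non-forced trials",
                     "stimchoice_validation_error")
  if (!all(df$order %in% c("AB", "BA")))
    abort_stimchoice("order must be AB or BA", "stimchoice_validation_error")
  if (!all(df$side_A %in% c("left", "right")))
    abort_stimchoice("side_A must be left or right", "stimchoice_validation_error")
  invisible(df)
}

#' Read and write the canonical trial table
#'
#' The canonical format is a tab-separated table, one row per trial, columns
#' `session_id, trial_index (0-based), condition_window, condition_level,
#' q_A, q_B, order (AB|BA), side_A (left|right), forced (0|1), stim_on
#' (0|1), choice (A|B|NA), error_code (string|NA), rt_ms (float|NA)`.
#' Missing values are encoded `NA`; unknown extra columns are preserved.
#' `write_trials()` then `read_trials()` is the identity on canonical
#' tables.
#'
#' @param path file path.
#' @return `read_trials()`: the validated, canonicalized data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path))
    abort_stimchoice(paste("no such file:", path), "stimchoice_schema_error")
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = NA)
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing))
    abort_stimchoice(paste("missing mandatory column(s):",
                           paste(missing, collapse = ", ")),
                     "stimchoice_schema_error")
  df <- canonicalize_trials(df)
  validate_trials(df)
  df
}

#' @rdname read_trials
#' @param trials trial table to write.
#' @export
write_trials <- function(trials, path) {
  df <- canonicalize_trials(trials)
  validate_trials(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read and write run configuration
#'
#' Configuration is stored as JSON: `design` (arguments for
#' [make_design()]), `cells` (list of condition cells: `window`, `level`,
#' `n_sessions`, `truth` = arguments for [ground_truth()]), and `analysis`
#' options (`outlier_k`, `ellipse_level`, `alpha`, `min_trials`), each
#' defaulting to the analysis' standard values (k = 3, level = 0.90,
#' alpha = 0.01).
#'
#' @param path JSON file path.
#' @return `read_config()`: a named list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  validate_config(cfg)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

validate_config <- function(config) {
  stopifnot(is.list(config), !is.null(config$cells))
  config$design <- config$design %||% list()
  ana <- config$analysis %||% list()
  ana$outlier_k <- ana$outlier_k %||% 3
  ana$ellipse_level <- ana$ellipse_level %||% 0.90
  ana$alpha <- ana$alpha %||% 0.01
  ana$min_trials <- ana$min_trials %||% 10
  config$analysis <- ana
  config$cells <- lapply(config$cells, function(cl) {
    stopifnot(!is.null(cl$window), !is.null(cl$level), !is.null(cl$n_sessions))
    cl
  })
  config
}

config_cells <- function(config) {
  lapply(config$cells, function(cl) {
    truth_args <- cl$truth %||% list()
    truth_args$stim_window <- cl$window
    list(window = cl$window, level = cl$level,
         n_sessions = as.integer(cl$n_sessions),
         truth = do.call(ground_truth, truth_args))
  })
}
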