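#' Split one session's trials by stimulation status
#'
#' Partitions the trial table of a single session into stimOFF and stimON
#' groups. Forced trials are never stimulated and therefore always fall in
#' the stimOFF group; a forced trial flagged as stimulated is a validation
#' error, as is a session whose stimulated trials span more than one
#' stimulation window (window varies across, not within, sessions).
#'
#' @param trials trial table for one session.
#' @return A list with elements `stimOFF` and `stimON`.
#' @export
split_by_stim <- function(trials) {
  if (length(unique(trials$session_id)) != 1L)
    abort_stimchoice("split_by_stim expects trials from a single session",
                     "stimchoice_data_error")
  if (any(trials$forced == 1L & trials$stim_on == 1L))
    abort_stimchoice("forced trial flagged as stimulated",
                     "stimchoice_data_error")
  win <- unique(trials$condition_window[trials$stim_on == 1L])
  if (length(win) > 1L)
    abort_stimchoice("mixed stimulation windows within one session",
                     "stimchoice_data_error")
  list(stimOFF = trials[trials$stim_on == 0L, , drop = FALSE],
       stimON = trials[trials$stim_on == 1L, , drop = FALSE])
}

#' Error-rate and response-time summaries per stimulation group
#'
#' The error rate counts every trial that did not end in juice delivery
#' (initiation failures, center-fixation breaks, missed choices,
#' peripheral-fixation breaks) over all trials of the group. With
#' `exclude_no_initiation = TRUE`, trials the animal never initiated are
#' dropped from both numerator and denominator. Mean response time is taken
#' over non-error trials.
#'
#' @param trials trial table for one session.
#' @param exclude_no_initiation drop initiation failures from the error-rate
#'   computation.
#' @return Data frame with one row per group: `group`, `n_trials`,
#'   `n_errors`, `error_rate`, `mean_rt`.
#' @export
session_summaries <- function(trials, exclude_no_initiation = FALSE) {
  groups <- split_by_stim(trials)
  out <- lapply(names(groups), function(g) {
    tr <- groups[[g]]
    if (exclude_no_initiation) {
      tr <- tr[is.na(tr$error_code) | tr$error_code != "no_initiation", ,
               drop = FALSE]
    }
    n <- nrow(tr)
    n_err <- sum(!is.na(tr$error_code))
    data.frame(group = g, n_trials = n, n_errors = n_err,
               error_rate = if (n > 0) n_err / n else NA_real_,
               mean_rt = mean(tr$rt_ms, na.rm = TRUE))
  })
  do.call(rbind, out)
}

fit_one <- function(trials, kind, min_trials) {
  spec <- model_spec(kind)
  tryCatch({
    fit <- fit_probit(trials, spec, min_trials = min_trials)
    list(fit = fit, params = derive_params(fit), error = NULL)
  }, stimchoice_error = function(e) list(fit = NULL, params = NULL,
                                         error = conditionMessage(e)))
}

#' Analyze one session: fits, contrasts, value ranges, summaries
#'
#' Runs the full per-session analysis: splits trials by stimulation status,
#' fits all five probit models to each group, derives the behavioral
#' statistics, and forms the stimulation contrasts `delta_rho`, `delta_eta`,
#' `delta_epsilon` (from the order model, the canonical source of rho, eta,
#' epsilon) and the bias deltas of the other four models. Value ranges are
#' `dV_A = rho_stimOFF * max(qA)` and `dV_B = max(qB)` (minimum pinned at 0
#' drops whenever the session contains null offers; otherwise the minimum
#' offered quantity), with `dV = dV_A - dV_B` in juice-B value units. Error
#' rates and mean response times are computed per group. Individual model
#' failures are recorded without aborting the remaining models.
#'
#' @param trials trial table for one session.
#' @param min_trials minimum usable trials per fit.
#' @return An object of class `session_result`.
#' @export
analyze_session <- function(trials, min_trials = 10L) {
  groups <- split_by_stim(trials)
  fits <- lapply(groups, function(tr) {
    stats::setNames(lapply(MODEL_KINDS, function(k) fit_one(tr, k, min_trials)),
                    MODEL_KINDS)
  })
  get_par <- function(group, kind, what) {
    p <- fits[[group]][[kind]]$params
    if (is.null(p)) return(NA_real_)
    p[[what]]
  }
  rho_off <- get_par("stimOFF", "order", "rho")
  rho_on <- get_par("stimON", "order", "rho")
  eta_off <- get_par("stimOFF", "order", "eta")
  eta_on <- get_par("stimON", "order", "eta")

  deltas <- c(
    delta_rho = rho_on - rho_off,
    delta_eta = eta_on - eta_off,
    delta_epsilon = get_par("stimON", "order", "bias") -
      get_par("stimOFF", "order", "bias"),
    delta_xi = get_par("stimON", "side", "bias") -
      get_par("stimOFF", "side", "bias"),
    delta_theta_juice = get_par("stimON", "hyst_juice", "bias") -
      get_par("stimOFF", "hyst_juice", "bias"),
    delta_theta_side = get_par("stimON", "hyst_side", "bias") -
      get_par("stimOFF", "hyst_side", "bias"),
    delta_theta_order = get_par("stimON", "hyst_order", "bias") -
      get_par("stimOFF", "hyst_order", "bias"))

  nf <- trials$forced == 0L
  has_null_A <- any(trials$q_A == 0L)
  has_null_B <- any(trials$q_B == 0L)
  min_qA <- if (has_null_A) 0 else min(trials$q_A[nf])
  min_qB <- if (has_null_B) 0 else min(trials$q_B[nf])
  dV_A <- rho_off * (max(trials$q_A[nf]) - min_qA)
  dV_B <- max(trials$q_B[nf]) - min_qB

  summ <- session_summaries(trials)
  win <- unique(trials$condition_window)[1]
  lev <- unique(trials$condition_level)[1]

  structure(list(
    session_id = trials$session_id[1], window = win, level = lev,
    fits = fits, deltas = deltas,
    rho_off = rho_off, rho_on = rho_on,
    eta_off = eta_off, eta_on = eta_on,
    dV_A = dV_A, dV_B = dV_B, dV = dV_A - dV_B,
    summaries = summ,
    rho_source = "stimOFF order-model fit"), class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat("<session_result>", x$session_id, sprintf("(%s, %s)", x$window, x$level),
      "\n  rho:", round(x$rho_off, 3), "->", round(x$rho_on, 3),
      " eta:", round(x$eta_off, 3), "->", round(x$eta_on, 3),
      "\n  dV =", round(x$dV, 3), "\n")
  invisible(x)
}

#' @describeIn analyze_session long-format data frame of one session result
#'   (columns: session, model, group, parameter, value).
#' @param x a `session_result`.
#' @param ... unused.
#' @export
as.data.frame.session_result <- function(x, ...) {
  rows <- list()
  for (g in names(x$fits)) {
    for (k in names(x$fits[[g]])) {
      p <- x$fits[[g]][[k]]$params
      f <- x$fits[[g]][[k]]$fit
      if (is.null(p)) next
      rows[[length(rows) + 1L]] <- data.frame(
        session = x$session_id, model = k, group = g,
        parameter = c("a0_implied", "rho", "eta", p$bias_label, "loglik"),
        value = c(-p$eta * log(p$rho), p$rho, p$eta, p$bias, f$loglik))
    }
  }
  do.call(rbind, rows)
}

#' Collect per-session results into a wide population table
#'
#' One row per session with the condition labels, parameter values per stim
#' group, the stimulation contrasts, value ranges, and the error-rate and
#' response-time summaries — the input expected by the population-level
#' operations.
#'
#' @param results list of [analyze_session()] results.
#' @return A data frame, one row per session.
#' @export
sessions_to_df <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    gp <- function(group, kind, what) {
      p <- r$fits[[group]][[kind]]$params
      if (is.null(p)) NA_real_ else p[[what]]
    }
    s <- r$summaries
    data.frame(
      session_id = r$session_id, window = r$window, level = r$level,
      rho_off = r$rho_off, rho_on = r$rho_on,
      eta_off = r$eta_off, eta_on = r$eta_on,
      epsilon_off = gp("stimOFF", "order", "bias"),
      epsilon_on = gp("stimON", "order", "bias"),
      xi_off = gp("stimOFF", "side", "bias"),
      xi_on = gp("stimON", "side", "bias"),
      theta_juice_off = gp("stimOFF", "hyst_juice", "bias"),
      theta_juice_on = gp("stimON", "hyst_juice", "bias"),
      theta_side_off = gp("stimOFF", "hyst_side", "bias"),
      theta_side_on = gp("stimON", "hyst_side", "bias"),
      theta_order_off = gp("stimOFF", "hyst_order", "bias"),
      theta_order_on = gp("stimON", "hyst_order", "bias"),
      delta_rho = r$deltas[["delta_rho"]],
      delta_eta = r$deltas[["delta_eta"]],
      delta_epsilon = r$deltas[["delta_epsilon"]],
      delta_xi = r$deltas[["delta_xi"]],
      delta_theta_juice = r$deltas[["delta_theta_juice"]],
      delta_theta_side = r$deltas[["delta_theta_side"]],
      delta_theta_order = r$deltas[["delta_theta_order"]],
      dV_A = r$dV_A, dV_B = r$dV_B, dV = r$dV,
      error_rate_off = s$error_rate[s$group == "stimOFF"],
      error_rate_on = s$error_rate[s$group == "stimON"],
      mean_rt_off = s$mean_rt[s$group == "stimOFF"],
      mean_rt_on = s$mean_rt[s$group == "stimON"],
      stringsAsFactors = FALSE)
  }))
}

#' Single-model stimOFF/stimON contrast for one session
#'
#' Fits one probit model to each stimulation group of a session and returns
#' the derived parameters and their stimulation contrasts; for the order
#' model the value ranges `dV_A`, `dV_B`, `dV` are included (same
#' definitions as in [analyze_session()]). This is the light-weight path
#' when only one model is needed (e.g. the order model supplying rho, eta
#' and epsilon).
#'
#' @param trials trial table for one session.
#' @param kind model kind (see [model_spec()]).
#' @param min_trials minimum usable trials per fit.
#' @return A one-row data frame: session_id, window, level, off/on values of
#'   rho, eta and the model's bias, their deltas, and (order model only)
#'   dV_A, dV_B, dV.
#' @export
session_contrast <- function(trials, kind = "order", min_trials = 10L) {
  groups <- split_by_stim(trials)
  spec <- model_spec(kind)
  p_off <- derive_params(fit_probit(groups$stimOFF, spec, min_trials = min_trials))
  p_on <- derive_params(fit_probit(groups$stimON, spec, min_trials = min_trials))
  out <- data.frame(
    session_id = trials$session_id[1],
    window = unique(trials$condition_window)[1],
    level = unique(trials$condition_level)[1],
    model = kind,
    rho_off = p_off$rho, rho_on = p_on$rho,
    eta_off = p_off$eta, eta_on = p_on$eta,
    bias_off = p_off$bias, bias_on = p_on$bias,
    delta_rho = p_on$rho - p_off$rho,
    delta_eta = p_on$eta - p_off$eta,
    delta_bias = p_on$bias - p_off$bias,
    unreliable = p_off$unreliable || p_on$unreliable,
    stringsAsFactors = FALSE)
  if (kind == "order") {
    nf <- trials$forced == 0L
    min_qA <- if (any(trials$q_A == 0L)) 0 else min(trials$q_A[nf])
    min_qB <- if (any(trials$q_B == 0L)) 0 else min(trials$q_B[nf])
    out$dV_A <- p_off$rho * (max(trials$q_A[nf]) - min_qA)
    out$dV_B <- max(trials$q_B[nf]) - min_qB
    out$dV <- out$dV_A - out$dV_B
  }
  out
}
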