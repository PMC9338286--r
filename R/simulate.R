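ERROR_CODES <- c("no_initiation", "break_center_fixation",
                 "no_choice", "break_peripheral_fixation")

#' Simulate one choice session
#'
#' Generates the trial-by-trial record of one session under the probit
#' choice model. On each non-forced trial the probability of choosing juice
#' B is \eqn{\Phi(X)} with
#' \deqn{X = \eta \log(V_B/V_A) + \epsilon (\delta_{AB} - \delta_{BA})
#'        + \xi (\delta_{A,right} - \delta_{B,right}) + \theta\textrm{-terms}}
#' where \eqn{V_A = \rho q_A}, \eqn{V_B = q_B}, so that the offer-value term
#' equals \eqn{a_0 + a_1 \log(q_B/q_A)} with \eqn{a_1 = \eta} and
#' \eqn{a_0 = -\eta \log\rho}. Hysteresis terms reference the most recent
#' trial with a valid choice (forced choices included); before any valid
#' choice they contribute 0.
#'
#' Stimulated trials (always a subset of non-forced trials) receive the
#' truth's stimulation effects: each offer value is shifted by
#' `value_shift_gain` times that juice's value range, the order bias is
#' shifted by `delta_epsilon`, and, when stimulation is delivered during
#' offer2, the steepness is multiplied by `eta_gain`. Error trials (drawn at
#' the per-group error rate) carry an error code and no choice; forced
#' trials otherwise always select the non-null offer.
#'
#' @param truth a [ground_truth()] object.
#' @param design a [make_design()] object.
#' @param seed integer seed; identical (truth, design, seed) give identical
#'   output.
#' @param session_id session label written into the table.
#' @param condition_level current-level label (annotation only; effect
#'   magnitudes come from `truth`).
#' @return A data frame, one row per trial, in the canonical trial-table
#'   schema (see [read_trials()]).
#' @export
simulate_session <- function(truth, design, seed, session_id = "s001",
                             condition_level = "<=15") {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "choice_design"))
  tr <- design$trials
  n <- nrow(tr)
  stim <- tr$stim_on == 1L
  if (truth$stim_window == "none") stim[] <- FALSE
  forced <- tr$forced == 1L
  if (any(stim & forced))
    abort_stimchoice("forced trials cannot be stimulated",
                     "stimchoice_design_error")

  # session value ranges (null offers pin the minimum at 0 drops)
  dV_A <- truth$rho * max(tr$q_A)
  dV_B <- max(tr$q_B)

  V_A <- truth$rho * tr$q_A
  V_B <- as.numeric(tr$q_B)
  if (truth$value_shift_gain != 0) {
    V_A[stim] <- V_A[stim] + truth$value_shift_gain * dV_A
    V_B[stim] <- V_B[stim] + truth$value_shift_gain * dV_B
  }
  eta_eff <- rep(truth$eta, n)
  if (truth$stim_window == "offer2") eta_eff[stim] <- truth$eta * truth$eta_gain
  eps_eff <- rep(truth$epsilon, n)
  eps_eff[stim] <- truth$epsilon + truth$delta_epsilon

  order_sign <- ifelse(tr$order == "AB", 1, -1)     # delta_AB - delta_BA
  side_sign <- ifelse(tr$side_A == "right", 1, -1)  # delta_A,right - delta_B,right
  x_base <- ifelse(forced, NA_real_,
                   eta_eff * log(V_B / V_A) + eps_eff * order_sign +
                     truth$xi * side_sign)

  err_rate <- ifelse(stim, truth$error_rate_on, truth$error_rate_off)
  rtp <- truth$rt_params

  with_seed(seed, {
    u_err <- stats::runif(n)
    u_choice <- stats::runif(n)
    err_code_draw <- sample(ERROR_CODES, n, replace = TRUE,
                            prob = truth$error_mix)
    rt_draw <- ifelse(stim,
                      stats::rlnorm(n, rtp$meanlog_on, rtp$sdlog_on),
                      stats::rlnorm(n, rtp$meanlog_off, rtp$sdlog_off))
  })
  is_err <- u_err < err_rate

  choice <- rep(NA_character_, n)
  any_hyst <- truth$theta_juice != 0 || truth$theta_side != 0 ||
    truth$theta_order != 0

  side_B <- ifelse(tr$side_A == "left", "right", "left")
  pos_B <- ifelse(tr$order == "AB", 2L, 1L)  # presentation slot of juice B

  if (!any_hyst) {
    p <- stats::pnorm(x_base)
    pick_B <- !is_err & !forced & u_choice < p
    pick_A <- !is_err & !forced & !pick_B
    choice[pick_B] <- "B"
    choice[pick_A] <- "A"
    choice[!is_err & forced] <- ifelse(tr$q_A[!is_err & forced] > 0, "A", "B")
  } else {
    prev_juice <- 0L      # +1 = B, -1 = A, 0 = undefined
    prev_side <- NA_character_
    prev_pos <- NA_integer_
    for (i in seq_len(n)) {
      if (is_err[i]) next
      if (forced[i]) {
        ch <- if (tr$q_A[i] > 0) "A" else "B"
      } else {
        x <- x_base[i]
        if (prev_juice != 0L) {
          x <- x + truth$theta_juice * prev_juice +
            truth$theta_side * (if (side_B[i] == prev_side) 1 else -1) +
            truth$theta_order * (if (pos_B[i] == prev_pos) 1 else -1)
        }
        ch <- if (u_choice[i] < stats::pnorm(x)) "B" else "A"
      }
      choice[i] <- ch
      if (ch == "B") {
        prev_juice <- 1L; prev_side <- side_B[i]; prev_pos <- pos_B[i]
      } else {
        prev_juice <- -1L
        prev_side <- if (side_B[i] == "left") "right" else "left"
        prev_pos <- 3L - pos_B[i]
      }
    }
  }

  data.frame(
    session_id = session_id,
    trial_index = 0:(n - 1L),
    condition_window = truth$stim_window,
    condition_level = condition_level,
    q_A = as.integer(tr$q_A), q_B = as.integer(tr$q_B),
    order = tr$order, side_A = tr$side_A,
    forced = as.integer(forced), stim_on = as.integer(stim),
    choice = choice,
    error_code = ifelse(is_err, err_code_draw, NA_character_),
    rt_ms = ifelse(is_err, NA_real_, rt_draw),
    stringsAsFactors = FALSE)
}

#' Simulate a multi-session stimulation experiment
#'
#' Runs [simulate_session()] over a grid of condition cells (stimulation
#' window x current-level label), mirroring an experiment in which current
#' level and window vary across sessions. Each cell carries its own ground
#' truth and session count; per-session seeds and design shuffles are
#' derived reproducibly from `seed`.
#'
#' @param cells a list of cells, each a list with elements `window`
#'   (`"offer1"`/`"offer2"`), `level` (label), `n_sessions`, and `truth`
#'   (a [ground_truth()] whose `stim_window` matches `window`).
#' @param design_args list of arguments for [make_design()] (minus `seed`),
#'   shared across sessions.
#' @param design_grid optional list of design-argument lists cycled over
#'   sessions (each merged over `design_args`). Real experiments pair
#'   different juices across sessions, so offered quantity ranges — and with
#'   them the value-range difference that drives the range-dependent bias —
#'   vary session to session; the grid emulates that variation.
#' @param seed master integer seed.
#' @param session_prefix prefix for generated session ids.
#' @return A list with `trials` (all sessions, canonical schema) and
#'   `manifest` (one row per session: ids, condition, ground-truth
#'   parameters, seeds).
#' @export
simulate_experiment <- function(cells, design_args = list(),
                                design_grid = NULL, seed = 1,
                                session_prefix = "s") {
  stopifnot(is.list(cells), length(cells) >= 1)
  n_total <- sum(vapply(cells, function(cl) as.integer(cl$n_sessions), 1L))
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                             2L * n_total), ncol = 2L))
  trials <- vector("list", n_total)
  man <- vector("list", n_total)
  k <- 0L
  for (cl in cells) {
    stopifnot(!is.null(cl$window), !is.null(cl$level),
              inherits(cl$truth, "ground_truth"))
    if (cl$truth$stim_window != cl$window)
      abort_stimchoice("cell window does not match truth$stim_window",
                       "stimchoice_design_error")
    for (j in seq_len(cl$n_sessions)) {
      k <- k + 1L
      sid <- sprintf("%s%03d", session_prefix, k)
      dargs <- design_args
      if (!is.null(design_grid)) {
        g <- design_grid[[((k - 1L) %% length(design_grid)) + 1L]]
        dargs <- utils::modifyList(dargs, g)
      }
      des <- do.call(make_design, c(dargs, list(seed = seeds[k, 1L])))
      trials[[k]] <- simulate_session(cl$truth, des, seed = seeds[k, 2L],
                                      session_id = sid,
                                      condition_level = as.character(cl$level))
      tru <- cl$truth
      man[[k]] <- data.frame(
        session_id = sid, window = cl$window, level = as.character(cl$level),
        rho = tru$rho, eta = tru$eta, epsilon = tru$epsilon, xi = tru$xi,
        theta_juice = tru$theta_juice, theta_side = tru$theta_side,
        theta_order = tru$theta_order,
        value_shift_gain = tru$value_shift_gain,
        delta_epsilon = tru$delta_epsilon, eta_gain = tru$eta_gain,
        error_rate_off = tru$error_rate_off, error_rate_on = tru$error_rate_on,
        design_seed = seeds[k, 1L], session_seed = seeds[k, 2L],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, man)
  if (anyDuplicated(manifest$session_id))
    abort_stimchoice("duplicate session ids", "stimchoice_design_error")
  list(trials = do.call(rbind, trials), manifest = manifest)
}
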