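MODEL_KINDS <- c("order", "side", "hyst_juice", "hyst_side", "hyst_order")

BIAS_LABELS <- c(order = "epsilon", side = "xi", hyst_juice = "theta_juice",
                 hyst_side = "theta_side", hyst_order = "theta_order")

#' Specify one of the five probit choice models
#'
#' All five models share the linear predictor
#' `X = a0 + a1 * log(qB/qA) + a2 * x2` with `P(choice B) = pnorm(X)`; they
#' differ only in the bias regressor `x2`, a difference of two indicator
#' variables taking values in \{-1, 0, +1\}:
#' \describe{
#'   \item{order}{`+1` on AB trials (juice A offered first), `-1` on BA
#'     trials. Bias `epsilon = a2`; `epsilon < 0` favors offer1.}
#'   \item{side}{`+1` when the juice-A target is on the right, `-1` when on
#'     the left. Bias `xi = a2`; since `x2 = +1` makes choosing B (the left
#'     target) more likely when `xi > 0`, a positive `xi` is a left-side
#'     preference.}
#'   \item{hyst_juice}{`+1` if the previous valid choice was juice B, `-1`
#'     if juice A. `theta_juice > 0` repeats the previous juice.}
#'   \item{hyst_side}{`+1` if the juice-B target occupies the side chosen on
#'     the previous valid trial. `theta_side > 0` repeats the side.}
#'   \item{hyst_order}{`+1` if juice B occupies the presentation slot
#'     (first/second) of the previously chosen juice. `theta_order > 0`
#'     repeats by order.}
#' }
#' `x2 = 0` only when the indicator pair is undefined (hysteresis models
#' before any valid choice exists); such trials are excluded from hysteresis
#' fits.
#'
#' @param kind one of `"order"`, `"side"`, `"hyst_juice"`, `"hyst_side"`,
#'   `"hyst_order"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = MODEL_KINDS) {
  kind <- match.arg(kind)
  structure(list(kind = kind, bias_label = BIAS_LABELS[[kind]],
                 hysteresis = startsWith(kind, "hyst")),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$kind, " (bias:", x$bias_label, ")\n")
  invisible(x)
}

#' Build probit regressors for a trial table
#'
#' Computes, for every non-forced, non-error trial, the offer-value
#' regressor `x1 = log(qB/qA)`, the model-specific bias regressor `x2`, and
#' the response `y` (1 if juice B chosen). Forced trials (a null offer makes
#' `x1` undefined) and error trials are excluded with a reason. Hysteresis
#' regressors reference the most recent earlier trial with a valid choice
#' (forced choices count); trials with no such reference get `x2 = 0` and
#' `has_ref = FALSE`.
#'
#' @param trials trial table (canonical schema), time-ordered within the
#'   session.
#' @param spec a [model_spec()].
#' @return A list with `data` (data frame: trial_index, x1, x2, y, has_ref)
#'   and `excluded` (data frame: trial_index, reason).
#' @export
build_regressors <- function(trials, spec) {
  stopifnot(inherits(spec, "model_spec"))
  n <- nrow(trials)
  forced <- trials$forced == 1L
  is_err <- !is.na(trials$error_code)
  if (any(!forced & (trials$q_A <= 0 | trials$q_B <= 0)))
    abort_stimchoice("non-forced trial with non-positive quantity",
                     "stimchoice_data_error")

  side_B <- ifelse(trials$side_A == "left", "right", "left")
  pos_B <- ifelse(trials$order == "AB", 2L, 1L)

  if (spec$hysteresis) {
    # most recent valid choice before each trial
    ref_juice <- integer(n); ref_side <- rep(NA_character_, n)
    ref_pos <- rep(NA_integer_, n)
    pj <- 0L; ps <- NA_character_; pp <- NA_integer_
    valid <- !is_err & !is.na(trials$choice)
    for (i in seq_len(n)) {
      ref_juice[i] <- pj; ref_side[i] <- ps; ref_pos[i] <- pp
      if (valid[i]) {
        if (trials$choice[i] == "B") {
          pj <- 1L; ps <- side_B[i]; pp <- pos_B[i]
        } else {
          pj <- -1L
          ps <- if (side_B[i] == "left") "right" else "left"
          pp <- 3L - pos_B[i]
        }
      }
    }
    has_ref <- ref_juice != 0L
  } else {
    has_ref <- rep(TRUE, n)
  }

  x2 <- switch(spec$kind,
    order = ifelse(trials$order == "AB", 1, -1),
    side = ifelse(trials$side_A == "right", 1, -1),
    hyst_juice = as.numeric(ref_juice),
    hyst_side = ifelse(!has_ref, 0, ifelse(side_B == ref_side, 1, -1)),
    hyst_order = ifelse(!has_ref, 0, ifelse(pos_B == ref_pos, 1, -1)))

  keep <- !forced & !is_err & !is.na(trials$choice)
  reason <- rep(NA_character_, n)
  reason[forced] <- "forced"
  reason[is_err] <- "error"
  reason[!forced & !is_err & is.na(trials$choice)] <- "no_choice_recorded"
  if (spec$hysteresis) {
    drop_ref <- keep & !has_ref
    reason[drop_ref] <- "no_reference_choice"
    keep <- keep & has_ref
  }

  list(
    data = data.frame(trial_index = trials$trial_index[keep],
                      x1 = log(trials$q_B[keep] / trials$q_A[keep]),
                      x2 = x2[keep],
                      y = as.integer(trials$choice[keep] == "B"),
                      has_ref = has_ref[keep]),
    excluded = data.frame(trial_index = trials$trial_index[!keep],
                          reason = reason[!keep]))
}

# Probit likelihood machinery: concave log-likelihood maximized by Fisher
# scoring with step-halving; jittered restarts guard against a bad start
# (the optimum is unique, so restarts agree whenever they converge).
# All terms are computed in log space (pnorm(log.p = TRUE)), so no
# probability clipping is needed even far into the tails.
probit_loglik <- function(b, X, y) {
  sum(stats::pnorm((2 * y - 1) * drop(X %*% b), log.p = TRUE))
}

# One evaluation shared by likelihood, score and Fisher information.
probit_eval <- function(b, X, y, s) {
  eta <- drop(X %*% b)
  lp1 <- stats::pnorm(eta, log.p = TRUE)
  lp0 <- stats::pnorm(eta, lower.tail = FALSE, log.p = TRUE)
  logd <- stats::dnorm(eta, log = TRUE)
  logp <- y * lp1 + (1 - y) * lp0
  list(ll = sum(logp),
       resid = s * exp(logd - logp),      # score residual: s*phi/Phi(s*eta)
       w = exp(2 * logd - lp1 - lp0))     # Fisher weight: phi^2/(Phi*(1-Phi))
}

probit_fisher <- function(X, y, b0, tol = 1e-6, max_iter = 100L) {
  s <- 2 * y - 1
  b <- b0
  ev <- probit_eval(b, X, y, s)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    grad <- drop(crossprod(X, ev$resid))
    if (sqrt(sum(grad^2)) <= tol) { converged <- TRUE; break }
    H <- crossprod(X * ev$w, X)
    # tiny scaled ridge keeps the solve defined under (near-)singular
    # information without measurably perturbing the Newton direction
    diag(H) <- diag(H) + 1e-10 * (mean(diag(H)) + 1)
    step <- solve(H, grad)
    # step-halving on the (concave) log-likelihood
    h <- 1
    repeat {
      b_new <- b + h * step
      ev_new <- probit_eval(b_new, X, y, s)
      if (ev_new$ll >= ev$ll - 1e-12 || h < 1e-6) break
      h <- h / 2
    }
    b <- b_new; ev <- ev_new
    if (sqrt(sum(b^2)) > 60) break  # diverging (separation); stop here
  }
  list(coef = b, loglik = ev$ll, converged = converged)
}

#' Fit a probit choice model by maximum likelihood
#'
#' Maximizes the probit log-likelihood of `P(choice B) = pnorm(a0 + a1*x1 +
#' a2*x2)` by Fisher scoring with step-halving, from a data-driven start plus
#' five jittered restarts (the likelihood is concave, so restarts agree; the
#' best log-likelihood is kept). Convergence requires gradient norm <= 1e-6.
#' If the bias regressor is constant it is dropped and `a2` is `NA`.
#'
#' Complete (or quasi-complete) separation — a linear predictor that
#' classifies every observed choice perfectly — makes the MLE diverge; it is
#' detected from the fitted direction, the fit is flagged `separation =
#' TRUE`, and coefficients are reported at the optimizer's stopping point as
#' unreliable.
#'
#' @param trials trial table for one session group, or a data frame with
#'   columns `x1`, `x2`, `y` (then used as-is).
#' @param spec a [model_spec()].
#' @param min_trials minimum usable trials (default 10).
#' @param n_restarts number of jittered restarts (default 5).
#' @return An object of class `probit_fit`: coefficients `a0`, `a1`, `a2`,
#'   `loglik`, `converged`, `separation`, `n_used`, `spec`, `excluded`.
#' @export
fit_probit <- function(trials, spec, min_trials = 10L, n_restarts = 5L) {
  stopifnot(inherits(spec, "model_spec"))
  if (all(c("x1", "x2", "y") %in% names(trials)) && !("q_A" %in% names(trials))) {
    reg <- list(data = trials, excluded = data.frame(trial_index = integer(0),
                                                     reason = character(0)))
  } else {
    reg <- build_regressors(trials, spec)
  }
  dat <- reg$data
  n <- nrow(dat)
  if (n < min_trials)
    abort_stimchoice(sprintf("only %d usable trials (minimum %d)", n, min_trials),
                     "stimchoice_fit_error")
  if (length(unique(dat$x1)) < 2L)
    abort_stimchoice("fewer than 2 distinct log quantity ratios",
                     "stimchoice_fit_error")
  y <- dat$y
  if (all(y == 1L) || all(y == 0L))
    abort_stimchoice("degenerate outcomes: only one choice observed",
                     "stimchoice_fit_error")

  use_x2 <- stats::var(dat$x2) > 0
  X <- if (use_x2) cbind(1, dat$x1, dat$x2) else cbind(1, dat$x1)

  pbar <- min(max(mean(y), 0.02), 0.98)
  b_start <- c(stats::qnorm(pbar), rep(0, ncol(X) - 1L))
  best <- probit_fisher(X, y, b_start)
  # the log-likelihood is concave, so restarts jittered around the first
  # solution re-converge quickly; they guard against a pathological first run
  starts <- with_seed(10007L + n,
                      replicate(n_restarts,
                                best$coef + stats::rnorm(ncol(X), 0, 0.15),
                                simplify = FALSE))
  for (s in starts) {
    cand <- probit_fisher(X, y, s)
    if (cand$loglik > best$loglik + 1e-10 ||
        (cand$converged && !best$converged && cand$loglik >= best$loglik - 1e-8))
      best <- cand
  }

  # separation: the fitted direction exhibits a perfect (or weak) separator
  t_sep <- (2 * y - 1) * drop(X %*% best$coef)
  separation <- all(t_sep > 0) || (all(t_sep >= 0) && any(t_sep == 0) &&
                                     any(t_sep > 0))

  structure(list(
    a0 = best$coef[1], a1 = best$coef[2],
    a2 = if (use_x2) best$coef[3] else NA_real_,
    loglik = best$loglik, converged = best$converged,
    separation = separation, n_used = n, spec = spec,
    excluded = reg$excluded), class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("<probit_fit:%s> a0 = %.4f  a1 = %.4f  a2 = %s  logLik = %.3f  n = %d%s%s\n",
              x$spec$kind, x$a0, x$a1,
              if (is.na(x$a2)) "NA" else sprintf("%.4f", x$a2),
              x$loglik, x$n_used,
              if (!x$converged) "  [not converged]" else "",
              if (x$separation) "  [separation]" else ""))
  invisible(x)
}

#' Derive behavioral statistics from a probit fit
#'
#' Converts the fitted coefficients into the behavioral measures: relative
#' value `rho = exp(-a0/a1)` (the quantity ratio qB/qA at indifference),
#' sigmoid steepness `eta = a1`, and the bias coefficient `a2` tagged by the
#' model (`epsilon`, `xi`, `theta_juice`, `theta_side`, or `theta_order`).
#'
#' @param fit a [fit_probit()] result.
#' @param spec model specification; defaults to the one stored in `fit`.
#' @return An object of class `choice_params` with `rho`, `eta`, `bias`,
#'   `bias_label`, and an `unreliable` flag (separation, non-convergence, or
#'   `a1 = 0` making `rho` undefined).
#' @export
derive_params <- function(fit, spec = fit$spec) {
  stopifnot(inherits(fit, "probit_fit"))
  rho_ok <- is.finite(fit$a1) && fit$a1 != 0
  structure(list(
    rho = if (rho_ok) exp(-fit$a0 / fit$a1) else NA_real_,
    eta = fit$a1,
    bias = fit$a2,
    bias_label = spec$bias_label,
    unreliable = fit$separation || !fit$converged || !rho_ok),
    class = "choice_params")
}

#' @export
print.choice_params <- function(x, ...) {
  cat(sprintf("<choice_params> rho = %.4f  eta = %.4f  %s = %s%s\n",
              x$rho, x$eta, x$bias_label,
              if (is.na(x$bias)) "NA" else sprintf("%.4f", x$bias),
              if (x$unreliable) "  [unreliable]" else ""))
  invisible(x)
}
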