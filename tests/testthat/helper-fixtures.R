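# Shared fixtures: built in code, no files.

default_design_args <- list(qA_levels = 0:3, qB_levels = 0:6, rho = 2.2,
                            eta = 2.5, n_trials = 400)

quick_design <- function(seed = 1, ...) {
  do.call(make_design, utils::modifyList(default_design_args,
                                         list(seed = seed, ...)))
}

# A design wrapper around a hand-built trial grid, for fully controlled
# simulations (bypasses offer-type selection).
manual_design <- function(trials) {
  stopifnot(all(c("q_A", "q_B", "order", "side_A", "forced", "stim_on") %in%
                  names(trials)))
  structure(list(offer_types = unique(trials[, c("q_A", "q_B", "forced")]),
                 trials = trials, n_trials = nrow(trials),
                 rho_assumed = NA, eta_nominal = NA,
                 stim_fraction = mean(trials$stim_on),
                 forced_fraction = mean(trials$forced), seed = NA),
            class = "choice_design")
}

# Hand-built canonical trial table from parallel vectors.
manual_trials <- function(order, side_A, choice,
                          q_A = 1L, q_B = 2L, forced = 0L, stim_on = 0L,
                          error_code = NA_character_, session_id = "tst",
                          window = "offer2", level = "<=15",
                          rt_ms = 200) {
  n <- length(order)
  data.frame(session_id = session_id, trial_index = 0:(n - 1L),
             condition_window = window, condition_level = level,
             q_A = rep_len(q_A, n), q_B = rep_len(q_B, n),
             order = order, side_A = side_A,
             forced = rep_len(forced, n), stim_on = rep_len(stim_on, n),
             choice = choice, error_code = rep_len(error_code, n),
             rt_ms = ifelse(is.na(rep_len(error_code, n)), rep_len(rt_ms, n),
                            NA_real_),
             stringsAsFactors = FALSE)
}

noerr <- function(...) ground_truth(..., error_rate_off = 0, error_rate_on = 0)

# Independent probit MLE oracle: multi-start Nelder-Mead on the likelihood,
# written without reference to the package's Fisher-scoring path.
oracle_probit_loglik <- function(b, X, y) {
  p <- stats::pnorm(drop(X %*% b))
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  sum(ifelse(y == 1, log(p), log1p(-p)))
}

oracle_probit_fit <- function(x1, x2, y, n_starts = 20) {
  X <- if (is.null(x2)) cbind(1, x1) else cbind(1, x1, x2)
  best <- -Inf
  for (s in seq_len(n_starts)) {
    b0 <- stats::rnorm(ncol(X), 0, 1.5)
    o <- stats::optim(b0, function(b) -oracle_probit_loglik(b, X, y),
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    o <- stats::optim(o$par, function(b) -oracle_probit_loglik(b, X, y),
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    if (-o$value > best) best <- -o$value
  }
  best
}

# Exact two-tailed signed-rank p by brute-force enumeration of all 2^n sign
# assignments (independent of the package's convolution implementation).
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
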