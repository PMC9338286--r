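# Hand-built 6-trial sequence exercising every regressor, including an error
# trial (t2) and a forced trial (t4) that updates the hysteresis reference:
#  t0 AB  A-left   choice A      t3 AB  A-left  choice B
#  t1 BA  A-right  choice B      t4 BA  A-right forced choice A (qB = 0)
#  t2 AB  A-right  error         t5 BA  A-left  choice A
hand_trials <- function() {
  tr <- manual_trials(
    order = c("AB", "BA", "AB", "AB", "BA", "BA"),
    side_A = c("left", "right", "right", "left", "right", "left"),
    choice = c("A", "B", NA, "B", "A", "A"),
    error_code = c(NA, NA, "break_center_fixation", NA, NA, NA))
  tr$forced[5] <- 1L
  tr$q_A[5] <- 2L; tr$q_B[5] <- 0L
  tr
}

test_that("bias regressors match hand-derived values for all five models", {
  tr <- hand_trials()
  reg <- function(kind) build_regressors(tr, model_spec(kind))
  # order/side: trials t0,t1,t3,t5 are usable (t2 error, t4 forced)
  r_ord <- reg("order")
  expect_equal(r_ord$data$trial_index, c(0, 1, 3, 5))
  expect_equal(r_ord$data$x2, c(1, -1, 1, -1))
  expect_equal(r_ord$data$y, c(0, 1, 1, 0))
  expect_equal(r_ord$data$x1, rep(log(2), 4))
  expect_setequal(r_ord$excluded$reason[r_ord$excluded$trial_index == 2],
                  "error")
  expect_setequal(r_ord$excluded$reason[r_ord$excluded$trial_index == 4],
                  "forced")
  expect_equal(reg("side")$data$x2, c(-1, 1, -1, -1))
  # hysteresis: t0 has no reference choice and is excluded
  r_hj <- reg("hyst_juice")
  expect_equal(r_hj$data$trial_index, c(1, 3, 5))
  expect_equal(r_hj$data$x2, c(-1, 1, -1))
  expect_equal(r_hj$excluded$reason[r_hj$excluded$trial_index == 0],
               "no_reference_choice")
  expect_equal(reg("hyst_side")$data$x2, c(1, -1, 1))
  expect_equal(reg("hyst_order")$data$x2, c(1, -1, -1))
})

test_that("non-positive quantities on non-forced trials are a data error", {
  tr <- hand_trials()
  tr$q_A[1] <- 0L
  expect_error(build_regressors(tr, model_spec("order")),
               class = "stimchoice_data_error")
})

test_that("exactly-identified two-point design recovers the inverse-normal solution", {
  # P(B) = 0.1587 at x1 = -1 and 0.8413 at x1 = +1  =>  (a0, a1) ~ (0, 1)
  n <- 10000
  mk <- function(x1, k) data.frame(x1 = x1, x2 = 0,
                                   y = rep(c(1L, 0L), c(k, n - k)))
  dat <- rbind(mk(-1, 1587), mk(1, 8413))
  fit <- fit_probit(dat, model_spec("order"))
  expect_true(fit$converged && !fit$separation)
  expect_true(is.na(fit$a2))  # constant bias regressor dropped
  q1 <- qnorm(1587 / n); q2 <- qnorm(8413 / n)
  expect_equal(fit$a0, (q1 + q2) / 2, tolerance = 1e-4)
  expect_equal(fit$a1, (q2 - q1) / 2, tolerance = 1e-4)
})

test_that("fitted log-likelihood matches a multi-start Nelder-Mead oracle", {
  set.seed(404)
  for (i in 1:10) {
    repeat {
      x1 <- runif(30, -1.5, 1.5)
      x2 <- sample(c(-1, 1), 30, replace = TRUE)
      y <- as.integer(runif(30) < pnorm(0.3 + 0.8 * x1 - 0.2 * x2))
      fit <- tryCatch(fit_probit(data.frame(x1, x2, y), model_spec("order")),
                      stimchoice_error = function(e) NULL)
      if (!is.null(fit) && !fit$separation) break
    }
    expect_lt(abs(fit$loglik - oracle_probit_fit(x1, x2, y)), 1e-6)
  }
})

test_that("perfect separators are detected and flagged", {
  x1 <- c(-2, -1.5, -1, -0.5, -0.1, 0.1, 0.5, 1, 1.5, 2, -0.7, 0.7)
  dat <- data.frame(x1 = x1, x2 = rep(c(-1, 1), 6), y = as.integer(x1 > 0))
  fit <- fit_probit(dat, model_spec("order"))
  expect_true(fit$separation)
  expect_true(derive_params(fit)$unreliable)
})

test_that("degenerate inputs raise fit errors", {
  dat <- data.frame(x1 = runif(20), x2 = rep(c(-1, 1), 10), y = rep(1L, 20))
  expect_error(fit_probit(dat, model_spec("order")),
               class = "stimchoice_fit_error")
  expect_error(fit_probit(dat[1:5, ], model_spec("order")),
               class = "stimchoice_fit_error")
  same_x1 <- data.frame(x1 = rep(1, 20), x2 = rep(c(-1, 1), 10),
                        y = rep(c(0L, 1L), 10))
  expect_error(fit_probit(same_x1, model_spec("order")),
               class = "stimchoice_fit_error")
})

test_that("derived parameters follow the closed-form identities", {
  mkfit <- function(a0, a1, a2) structure(
    list(a0 = a0, a1 = a1, a2 = a2, loglik = -1, converged = TRUE,
         separation = FALSE, n_used = 100, spec = model_spec("order")),
    class = "probit_fit")
  expect_equal(derive_params(mkfit(0, 1.7, 0))$rho, 1)
  p <- derive_params(mkfit(-1.3863, 2, -0.2))
  expect_equal(p$rho, 2, tolerance = 1e-4)  # exp(0.69315)
  expect_equal(p$eta, 2)
  expect_equal(p$bias, -0.2)            # epsilon < 0: bias favoring offer1
  expect_equal(p$bias_label, "epsilon")
  # a1 = 0 leaves rho undefined and flagged
  p0 <- derive_params(mkfit(1, 0, 0))
  expect_true(is.na(p0$rho) && p0$unreliable)
})

test_that("likelihood is invariant to relabeling and equivariant in x2", {
  tru <- noerr(rho = 2.2, eta = 2.5, epsilon = -0.3, stim_window = "none")
  tr <- simulate_session(tru, quick_design(seed = 14), seed = 33)
  fit <- fit_probit(tr, model_spec("order"))
  # left/right relabeling does not enter the order model
  flipped <- tr
  flipped$side_A <- ifelse(tr$side_A == "left", "right", "left")
  fit_f <- fit_probit(flipped, model_spec("order"))
  expect_equal(fit_f$loglik, fit$loglik, tolerance = 1e-10)
  expect_equal(c(fit_f$a0, fit_f$a1, fit_f$a2), c(fit$a0, fit$a1, fit$a2),
               tolerance = 1e-8)
  # negating the bias regressor negates a2 (and only a2)
  reg <- build_regressors(tr, model_spec("order"))$data
  neg <- reg; neg$x2 <- -reg$x2
  fit_n <- fit_probit(neg, model_spec("order"))
  expect_equal(fit_n$a2, -fit$a2, tolerance = 1e-6)
  expect_equal(fit_n$a1, fit$a1, tolerance = 1e-6)
  expect_equal(fit_n$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("fitted choice probability is monotone in the offers when a1 > 0", {
  tru <- noerr(rho = 2.2, eta = 2.5, stim_window = "none")
  tr <- simulate_session(tru, quick_design(seed = 15), seed = 41)
  fit <- fit_probit(tr, model_spec("order"))
  expect_gt(fit$a1, 0)
  qB <- 1:10
  p_qB <- pnorm(fit$a0 + fit$a1 * log(qB / 2))   # qA fixed
  p_qA <- pnorm(fit$a0 + fit$a1 * log(4 / qB))   # qB fixed, qA varies
  expect_true(all(diff(p_qB) >= 0) && all(diff(p_qA) <= 0))
})
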