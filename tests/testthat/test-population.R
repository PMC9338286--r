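test_that("exact Wilcoxon matches hand cases and handles zeros", {
  # n = 6, all differences negative: W+ = 0, two-tailed p = 2/2^6
  expect_equal(wilcoxon_signed_rank(-(1:6))$p, 0.03125)
  # antisymmetric pairs leave W+ at its null mean
  w <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3))
  expect_gte(w$p, 0.99)
  # all zero differences: p = 1 with the flag set
  wz <- wilcoxon_signed_rank(rep(0, 8))
  expect_equal(wz$p, 1)
  expect_true(wz$all_zero)
  # agreement with R's reference implementation when there are no ties
  set.seed(61)
  d <- round(rnorm(12), 3)
  expect_equal(wilcoxon_signed_rank(d)$p,
               suppressWarnings(wilcox.test(d, exact = TRUE)$p.value))
})

test_that("exact Wilcoxon equals the 2^n enumeration oracle (with ties)", {
  set.seed(303)
  for (i in 1:8) {
    n <- sample(5:10, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE)  # forces ties
    expect_equal(wilcoxon_signed_rank(d)$p, oracle_wilcoxon_p(d))
  }
})

test_that("paired tests report both p values and the mean difference", {
  set.seed(9)
  off <- rnorm(20); on <- off + 0.5 + rnorm(20, sd = 0.3)
  pt <- paired_tests(off, on)
  expect_lt(pt$p_wilcoxon, 0.01)
  expect_lt(pt$p_ttest, 0.01)
  expect_equal(pt$mean_diff, mean(on - off))
  expect_equal(pt$p_ttest, t.test(on - off)$p.value)
  expect_error(paired_tests(1:3, 2:4), class = "stimchoice_data_error")
})

test_that("3-SD outlier rule matches direct arithmetic on the worked example", {
  # 20 zeros plus one 10 on both axes: z = (10 - 10/21)/sd > 3
  x <- c(rep(0, 20), 10)
  z <- abs(x - mean(x)) / sd(x)
  expect_gt(z[21], 3)          # about 4.37
  expect_true(all(z[1:20] < 3))
  rm1 <- remove_outliers(cbind(x, x))
  expect_equal(rm1$removed, 21L)
  expect_equal(rm1$kept, 1:20)
  # all identical points: sd = 0 on both axes, nothing removed, flagged
  rm2 <- remove_outliers(cbind(rep(1, 10), rep(2, 10)))
  expect_equal(rm2$n_removed, 0L)
  expect_equal(rm2$degenerate_axes, c(1L, 2L))
  # a point >5 SD out on one axis only is removed
  y <- c(rnorm(30), 0)
  y[31] <- mean(y[1:30]) + 6 * sd(y[1:30])
  expect_true(31L %in% remove_outliers(cbind(y, rnorm(31)))$removed)
})

test_that("outlier rule keeps standard-normal clouds intact most of the time", {
  set.seed(5150)
  none_removed <- replicate(60, {
    remove_outliers(matrix(rnorm(100), ncol = 2))$n_removed == 0
  })
  expect_gte(mean(none_removed), 0.85)
})

test_that("confidence ellipse uses the chi-square Mahalanobis radius", {
  # points constructed so the sample covariance is exactly the identity
  pts <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) * sqrt(3 / 2)
  ell <- confidence_ellipse(pts, level = 0.90)
  expect_equal(unname(ell$center), c(0, 0))
  expect_equal(unname(ell$semi_axes), rep(sqrt(qchisq(0.90, 2)), 2),
               tolerance = 1e-10)  # ~2.1460
  # rotation equivariance
  set.seed(17)
  cloud <- matrix(rnorm(200), ncol = 2) %*% matrix(c(2, 0.6, 0.6, 1), 2)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  e1 <- confidence_ellipse(cloud)
  e2 <- confidence_ellipse(cloud %*% t(R))
  expect_equal(sort(e2$semi_axes), sort(e1$semi_axes), tolerance = 1e-8)
  expect_equal(unname(e2$center), drop(R %*% e1$center), tolerance = 1e-8)
  d_angle <- (e2$angle - (e1$angle + th)) %% pi
  expect_true(min(d_angle, pi - d_angle) < 1e-6)
  # singular covariance errors
  expect_error(confidence_ellipse(cbind(1:5, 2 * (1:5))),
               class = "stimchoice_data_error")
})

test_that("ellipse coverage is close to nominal on a large normal sample", {
  set.seed(23)
  n <- 20000
  pts <- matrix(rnorm(2 * n), ncol = 2) %*% matrix(c(1.5, 0.4, 0.4, 0.8), 2)
  ell <- confidence_ellipse(pts, level = 0.90)
  S <- cov(pts); mu <- colMeans(pts)
  md2 <- stats::mahalanobis(pts, mu, S)
  coverage <- mean(md2 <= qchisq(0.90, 2))
  expect_lt(abs(coverage - 0.90), 0.02)
  # the ellipse boundary is exactly the chi-square Mahalanobis contour
  expect_equal(prod(ell$semi_axes)^2, det(S) * qchisq(0.9, 2)^2,
               tolerance = 1e-6)
})

test_that("effect rectification applies the stated signs", {
  expect_equal(rectify_effect(-0.5, "choice_variability"), 0.5)
  expect_equal(rectify_effect(-0.3, "order_bias", "offer2"), 0.3)
  expect_equal(rectify_effect(-0.3, "order_bias", "offer1"), -0.3)
  expect_equal(rectify_effect(c(-1, 2), "order_bias", c("offer1", "offer2")),
               c(-1, -2))
  expect_error(rectify_effect(1, "nope"), class = "stimchoice_data_error")
})

test_that("range bias recovers collinearity and rejects degenerate input", {
  s <- data.frame(level = "50", delta_rho = c(1, 2, 3, 4, 5) * 0.1,
                  dV = c(1, 2, 3, 4, 5))
  rb <- range_bias(s, remove_outliers_k = NULL)
  expect_equal(rb$r, 1)
  s0 <- data.frame(level = "50", delta_rho = rnorm(5), dV = rep(2, 5))
  expect_error(range_bias(s0, remove_outliers_k = NULL),
               class = "stimchoice_data_error")
})

test_that("max-normalization is exact, idempotent, and guards its domain", {
  tab <- data.frame(family = "choice_variability", mean = c(4, 2, 1))
  n1 <- normalize_effects(tab)
  expect_equal(n1$normalized, c(1, 0.5, 0.25))
  n1$mean <- n1$normalized
  n2 <- normalize_effects(n1)
  expect_equal(n2$normalized, n1$normalized)
  expect_warning(normalize_effects(data.frame(family = "x", mean = c(-1, -2))),
                 "non-positive")
})

test_that("effect table carries rectified means, max 1 per family, flags", {
  set.seed(1234)
  # small two-condition experiment with a steepness effect in one cell only
  cells <- list(
    list(window = "offer2", level = "<=15", n_sessions = 8,
         truth = ground_truth(rho = 2.2, eta = 2.5, stim_window = "offer2",
                              eta_gain = 0.55)),
    list(window = "offer1", level = "<=15", n_sessions = 8,
         truth = ground_truth(rho = 2.2, eta = 2.5, stim_window = "offer1")))
  sim <- simulate_experiment(cells, design_args = default_design_args,
                             seed = 99)
  res <- lapply(split(sim$trials, sim$trials$session_id), analyze_session)
  tab <- suppressWarnings(effect_table(sessions_to_df(res)))
  # families with a positive effect normalize to a maximum of exactly 1;
  # a family with no positive condition mean is left NA (null order bias)
  for (fam in unique(tab$family)) {
    m <- tab$mean[tab$family == fam]
    if (max(m) > 0) expect_equal(max(tab$normalized[tab$family == fam]), 1)
    else expect_true(all(is.na(tab$normalized[tab$family == fam])))
  }
  dcv <- tab[tab$family == "choice_variability", ]
  expect_gt(dcv$mean[dcv$window == "offer2"], 0)   # -delta_eta > 0
  expect_equal(dcv$normalized[dcv$window == "offer2"], 1)
  expect_true(all(c("order_bias", "range_bias") %in% tab$family))
  expect_true(is.logical(tab$significant))
})
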