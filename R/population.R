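#' Exact two-tailed Wilcoxon signed-rank test
#'
#' Signed-rank test of symmetry of `d` about zero. Zero differences are
#' dropped (the classic treatment; the count is reported). For `n <=
#' exact_max` the null distribution of the positive-rank sum W+ is built by
#' exact enumeration over all 2^n sign assignments (computed by subset-sum
#' convolution over the — possibly tied, hence averaged — ranks), and the
#' two-tailed p value is `min(1, 2 * min(P(W+ <= w), P(W+ >= w)))`. Above
#' `exact_max` a normal approximation with continuity correction and
#' tie-corrected variance `sum(ranks^2)/4` is used.
#'
#' @param d numeric vector of paired differences.
#' @param exact_max largest n for which the exact distribution is used.
#' @return List: `p`, `statistic` (W+), `n` (nonzero differences),
#'   `n_zero`, `exact`, `all_zero` (if TRUE, `p = 1` by convention, flagged).
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 25L) {
  d <- d[is.finite(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p = 1, statistic = NA_real_, n = 0L, n_zero = n_zero,
                exact = TRUE, all_zero = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of 2*W+ over all 2^n sign assignments (doubled ranks are
    # integers even under midrank ties)
    r2 <- as.integer(round(2 * r))
    counts <- numeric(sum(r2) + 1L)  # index i -> sum i-1
    counts[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    tot <- 2^n
    w2 <- round(2 * W)
    p_le <- sum(counts[seq_len(w2 + 1L)]) / tot
    p_ge <- sum(counts[(w2 + 1L):length(counts)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    list(p = p, statistic = W, n = n, n_zero = n_zero, exact = TRUE,
         all_zero = FALSE)
  } else {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(sum(r^2) / 4)
    z <- (W - mu - sign(W - mu) * 0.5) / sigma
    list(p = min(1, 2 * stats::pnorm(-abs(z))), statistic = W, n = n,
         n_zero = n_zero, exact = FALSE, all_zero = FALSE)
  }
}

#' Paired population tests for a stimOFF/stimON contrast
#'
#' Two-tailed Wilcoxon signed-rank test (exact for small n, see
#' [wilcoxon_signed_rank()]) and two-tailed paired t test on the differences
#' `on - off`, as used for the session-by-session population comparisons.
#'
#' @param values_off,values_on equal-length paired vectors (one value per
#'   session).
#' @return List: `p_wilcoxon`, `p_ttest`, `mean_diff`, `n`, `all_zero`.
#' @export
paired_tests <- function(values_off, values_on) {
  stopifnot(length(values_off) == length(values_on))
  ok <- is.finite(values_off) & is.finite(values_on)
  d <- values_on[ok] - values_off[ok]
  if (length(d) < 5L)
    abort_stimchoice("paired_tests requires at least 5 complete pairs",
                     "stimchoice_data_error")
  w <- wilcoxon_signed_rank(d)
  p_t <- if (stats::sd(d) == 0) {
    if (all(d == 0)) 1 else 0
  } else {
    stats::t.test(d)$p.value
  }
  list(p_wilcoxon = w$p, p_ttest = p_t, mean_diff = mean(d), n = length(d),
       all_zero = w$all_zero)
}

#' Remove bivariate outliers by the 3-SD rule
#'
#' A point is an outlier if it lies more than `k` sample standard deviations
#' from the mean on either axis, with mean and SD computed once on the full
#' set (no iteration). An axis with zero SD removes nothing on that axis
#' (flagged).
#'
#' @param points two-column matrix or data frame (one row per session).
#' @param k SD multiplier (default 3).
#' @return List: `kept` and `removed` (row indices), `n_removed`,
#'   `degenerate_axes` (axes with zero SD).
#' @export
remove_outliers <- function(points, k = 3) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2L, nrow(pts) >= 3L)
  mu <- colMeans(pts)
  sdv <- apply(pts, 2L, stats::sd)
  out <- rep(FALSE, nrow(pts))
  degenerate <- which(sdv == 0)
  for (j in 1:2) {
    if (sdv[j] > 0) out <- out | abs(pts[, j] - mu[j]) > k * sdv[j]
  }
  list(kept = which(!out), removed = which(out), n_removed = sum(out),
       degenerate_axes = degenerate)
}

#' Bivariate confidence ellipse of a point cloud
#'
#' Ellipse containing the stated probability mass of a bivariate normal with
#' the sample mean and covariance: Mahalanobis radius `sqrt(qchisq(level,
#' 2))`, axes along the covariance eigenvectors with semi-axis lengths
#' `sqrt(eigenvalue * qchisq(level, 2))`.
#'
#' @param points two-column matrix or data frame, n >= 3.
#' @param level coverage level in (0, 1); default 0.90.
#' @return An object of class `ellipse_spec`: `center`, `semi_axes`,
#'   `angle` (radians, first axis vs x), `level`.
#' @export
confidence_ellipse <- function(points, level = 0.90) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2L, nrow(pts) >= 3L, level > 0, level < 1)
  S <- stats::cov(pts)
  if (!all(is.finite(S)) || det(S) <= .Machine$double.eps * max(diag(S))^2)
    abort_stimchoice("singular covariance; ellipse undefined",
                     "stimchoice_data_error")
  e <- eigen(S, symmetric = TRUE)
  q <- stats::qchisq(level, df = 2)
  structure(list(center = colMeans(pts),
                 semi_axes = sqrt(e$values * q),
                 angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                 level = level), class = "ellipse_spec")
}

#' @export
print.ellipse_spec <- function(x, ...) {
  cat(sprintf("<ellipse_spec> center (%.3f, %.3f), semi-axes (%.3f, %.3f), angle %.3f rad, level %.2f\n",
              x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
              x$angle, x$level))
  invisible(x)
}

#' Rectify a stimulation effect so the expected effect is positive
#'
#' Choice variability: `dcv = -delta_eta` regardless of window (a steepness
#' drop is a variability increase). Order bias: stimulation during offer1
#' is expected to increase, during offer2 to decrease, the order bias, so
#' offer2-session measures flip sign (`+delta_epsilon` for offer1,
#' `-delta_epsilon` for offer2).
#'
#' @param delta per-session delta (vectorized).
#' @param effect_kind `"choice_variability"` or `"order_bias"`.
#' @param window stimulation window per session (`"offer1"`/`"offer2"`;
#'   required for `"order_bias"`).
#' @return Rectified values.
#' @export
rectify_effect <- function(delta, effect_kind, window = NULL) {
  if (identical(effect_kind, "choice_variability")) return(-delta)
  if (identical(effect_kind, "order_bias")) {
    stopifnot(!is.null(window), all(window %in% c("offer1", "offer2")))
    return(ifelse(window == "offer2", -delta, delta))
  }
  abort_stimchoice(paste("unknown effect kind:", effect_kind),
                   "stimchoice_data_error")
}

#' Range-dependent bias per current level
#'
#' For each current level (stimulation windows pooled), Pearson's
#' correlation between the change in relative value `delta_rho` and the
#' difference in value range `dV = dV_A - dV_B` across sessions, with the
#' two-tailed correlation-test p value.
#'
#' @param sessions data frame with columns `level`, `delta_rho`, `dV` (one
#'   row per session), e.g. from [sessions_to_df()].
#' @param remove_outliers_k if non-`NULL`, apply [remove_outliers()] with
#'   this `k` to the (delta_rho, dV) cloud per level first.
#' @return Data frame: `level`, `n`, `r`, `p`, `n_outliers_removed`.
#' @export
range_bias <- function(sessions, remove_outliers_k = 3) {
  out <- lapply(unique(sessions$level), function(lv) {
    s <- sessions[sessions$level == lv, , drop = FALSE]
    s <- s[is.finite(s$delta_rho) & is.finite(s$dV), , drop = FALSE]
    n_rm <- 0L
    if (!is.null(remove_outliers_k) && nrow(s) >= 3L) {
      rm <- remove_outliers(cbind(s$delta_rho, s$dV), k = remove_outliers_k)
      n_rm <- rm$n_removed
      s <- s[rm$kept, , drop = FALSE]
    }
    if (nrow(s) < 3L)
      abort_stimchoice(sprintf("level %s: fewer than 3 usable sessions", lv),
                       "stimchoice_data_error")
    if (stats::sd(s$dV) == 0 || stats::sd(s$delta_rho) == 0)
      abort_stimchoice(sprintf("level %s: zero variance; correlation undefined", lv),
                       "stimchoice_data_error")
    ct <- stats::cor.test(s$delta_rho, s$dV, method = "pearson",
                          alternative = "two.sided")
    data.frame(level = lv, n = nrow(s), r = unname(ct$estimate),
               p = ct$p.value, n_outliers_removed = n_rm)
  })
  do.call(rbind, out)
}

#' Max-normalize condition effect sizes
#'
#' Divides each condition mean by the maximum over conditions within its
#' effect family, so the largest effect maps to exactly 1. Idempotent. A
#' family whose means are all non-positive is skipped with a warning
#' (normalized values set to `NA`).
#'
#' @param effects data frame with columns `family` and `mean` (plus
#'   anything else, preserved).
#' @return The input with a `normalized` column (replaced if present).
#' @export
normalize_effects <- function(effects) {
  stopifnot(all(c("family", "mean") %in% names(effects)))
  effects$normalized <- NA_real_
  for (fam in unique(effects$family)) {
    i <- effects$family == fam
    m <- max(effects$mean[i], na.rm = TRUE)
    if (!is.finite(m) || m <= 0) {
      warning(sprintf("family '%s': all condition means non-positive; normalization skipped",
                      fam))
      next
    }
    effects$normalized[i] <- effects$mean[i] / m
  }
  effects
}

#' Cross-condition effect-size table
#'
#' Builds the effect table over the window-by-current-level condition grid:
#' for each condition, the rectified change in choice variability
#' (`dcv = -delta_eta`) and the rectified change in order bias are averaged
#' across sessions (rectification before averaging), with standard errors
#' `sd/sqrt(n)` and two-tailed exact Wilcoxon signed-rank p values; the
#' range-dependent bias is summarized per current level (windows pooled,
#' 3-SD outliers removed) as Pearson's `r(delta_rho, dV)` with its
#' correlation-test p. Each family is then max-normalized so its largest
#' effect is 1, and conditions are flagged significant at `alpha`.
#'
#' @param sessions wide per-session data frame from [sessions_to_df()].
#' @param alpha significance threshold for the `significant` flag (default
#'   0.01).
#' @param outlier_k SD multiplier for the range-bias outlier rule.
#' @return Data frame: `family`, `window` (`NA` for the pooled range
#'   family), `level`, `n`, `mean`, `se`, `p`, `normalized`, `significant`.
#' @export
effect_table <- function(sessions, alpha = 0.01, outlier_k = 3) {
  conds <- unique(sessions[, c("window", "level")])
  rows <- list()
  for (i in seq_len(nrow(conds))) {
    w <- conds$window[i]; lv <- conds$level[i]
    s <- sessions[sessions$window == w & sessions$level == lv, , drop = FALSE]
    dcv <- rectify_effect(s$delta_eta, "choice_variability")
    dcv <- dcv[is.finite(dcv)]
    deps <- rectify_effect(s$delta_epsilon, "order_bias", s$window)
    deps <- deps[is.finite(deps)]
    rows[[length(rows) + 1L]] <- data.frame(
      family = "choice_variability", window = w, level = lv, n = length(dcv),
      mean = mean(dcv), se = stats::sd(dcv) / sqrt(length(dcv)),
      p = wilcoxon_signed_rank(dcv)$p)
    rows[[length(rows) + 1L]] <- data.frame(
      family = "order_bias", window = w, level = lv, n = length(deps),
      mean = mean(deps), se = stats::sd(deps) / sqrt(length(deps)),
      p = wilcoxon_signed_rank(deps)$p)
  }
  rb <- range_bias(sessions, remove_outliers_k = outlier_k)
  for (i in seq_len(nrow(rb))) {
    rows[[length(rows) + 1L]] <- data.frame(
      family = "range_bias", window = NA_character_, level = rb$level[i],
      n = rb$n[i], mean = rb$r[i], se = NA_real_, p = rb$p[i])
  }
  tab <- do.call(rbind, rows)
  tab <- normalize_effects(tab)
  tab$significant <- !is.na(tab$p) & tab$p < alpha
  rownames(tab) <- NULL
  tab
}

#' Population contrast for one parameter and window
#'
#' The session-scatter analysis behind the population figures: per
#' stimulation window, paired stimOFF vs stimON values of one behavioral
#' parameter, with the 3-SD outlier rule applied to the (off, on) cloud,
#' paired Wilcoxon and t tests, and the 90% confidence ellipse.
#'
#' @param sessions wide per-session data frame ([sessions_to_df()]).
#' @param parameter base name of the parameter (`"rho"`, `"eta"`,
#'   `"epsilon"`, `"xi"`, `"theta_juice"`, `"theta_side"`, `"theta_order"`,
#'   `"error_rate"`, `"mean_rt"`).
#' @param window `"offer1"` or `"offer2"`.
#' @param outlier_k SD multiplier for the outlier rule (`NULL` to skip).
#' @param ellipse_level coverage of the confidence ellipse.
#' @return List: `parameter`, `window`, `n`, `tests` ([paired_tests()]
#'   output), `ellipse`, `n_outliers_removed`.
#' @export
population_contrast <- function(sessions, parameter, window,
                                outlier_k = 3, ellipse_level = 0.90) {
  off <- sessions[[paste0(parameter, "_off")]]
  on <- sessions[[paste0(parameter, "_on")]]
  if (is.null(off) || is.null(on))
    abort_stimchoice(paste("unknown parameter:", parameter),
                     "stimchoice_data_error")
  sel <- sessions$window == window & is.finite(off) & is.finite(on)
  pts <- cbind(off[sel], on[sel])
  n_rm <- 0L
  if (!is.null(outlier_k) && nrow(pts) >= 3L) {
    rm <- remove_outliers(pts, k = outlier_k)
    n_rm <- rm$n_removed
    pts <- pts[rm$kept, , drop = FALSE]
  }
  list(parameter = parameter, window = window, n = nrow(pts),
       tests = paired_tests(pts[, 1], pts[, 2]),
       ellipse = tryCatch(confidence_ellipse(pts, level = ellipse_level),
                          stimchoice_error = function(e) NULL),
       n_outliers_removed = n_rm)
}
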