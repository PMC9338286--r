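#' Ground-truth parameters for a simulated choice session
#'
#' Bundles the generative counterparts of the behavioral statistics the
#' analysis estimates: the relative value `rho` (quantity ratio qB/qA at
#' indifference), the sigmoid steepness `eta` (probit slope per unit
#' log-quantity-ratio; inversely related to choice variability), the
#' presentation-order bias `epsilon` (negative favors offer1), the side bias
#' `xi` (positive favors the left target), and three choice-hysteresis
#' coefficients (tendency to repeat the previously chosen juice, side, or
#' presentation-order slot). Stimulation acts through three configurable
#' effects: a range-proportional value shift (`value_shift_gain`), an
#' additive order-bias shift (`delta_epsilon`), and a multiplicative gain on
#' the steepness (`eta_gain`, applied only when stimulation is delivered
#' during offer2, the window in which the decision is made).
#'
#' @param rho true relative value, > 0 (dimensionless quantity ratio).
#' @param eta true sigmoid steepness, > 0 (probit units per log ratio).
#' @param epsilon order-bias coefficient (probit units).
#' @param xi side-bias coefficient (probit units); positive = left bias.
#' @param theta_juice,theta_side,theta_order hysteresis coefficients
#'   (probit units).
#' @param stim_window one of `"offer1"`, `"offer2"`, `"none"`.
#' @param value_shift_gain fraction of each juice's value range added to its
#'   offer value on stimulated trials (range-adaptation effect).
#' @param delta_epsilon additive shift of the order bias on stimulated trials.
#' @param eta_gain multiplicative factor on `eta` for stimulated trials when
#'   `stim_window == "offer2"`; must be > 0; 1 = no effect.
#' @param error_rate_off,error_rate_on probability that a trial ends without
#'   juice delivery, per stimulation group.
#' @param error_mix mixture weights over the four error modes
#'   (no initiation, center-fixation break, no choice, peripheral-fixation
#'   break); normalized internally.
#' @param rt_meanlog,rt_sdlog log-normal response-time parameters (ms) for
#'   stimOFF trials.
#' @param rt_meanlog_on,rt_sdlog_on same for stimON trials; default equal to
#'   the stimOFF values (stimulation was found not to affect response times).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(rho, eta, epsilon = 0, xi = 0,
                         theta_juice = 0, theta_side = 0, theta_order = 0,
                         stim_window = c("none", "offer1", "offer2"),
                         value_shift_gain = 0, delta_epsilon = 0, eta_gain = 1,
                         error_rate_off = 0.12, error_rate_on = 0.12,
                         error_mix = c(no_initiation = 0.5,
                                       break_center_fixation = 0.3,
                                       no_choice = 0.1,
                                       break_peripheral_fixation = 0.1),
                         rt_meanlog = log(200), rt_sdlog = 0.15,
                         rt_meanlog_on = rt_meanlog, rt_sdlog_on = rt_sdlog) {
  stim_window <- match.arg(stim_window)
  stopifnot(is.numeric(rho), rho > 0, is.numeric(eta), eta > 0,
            is.numeric(eta_gain), eta_gain > 0,
            error_rate_off >= 0, error_rate_off <= 1,
            error_rate_on >= 0, error_rate_on <= 1,
            length(error_mix) == 4L, all(error_mix >= 0), sum(error_mix) > 0,
            rt_sdlog >= 0, rt_sdlog_on >= 0)
  structure(list(
    rho = rho, eta = eta, epsilon = epsilon, xi = xi,
    theta_juice = theta_juice, theta_side = theta_side,
    theta_order = theta_order,
    stim_window = stim_window,
    value_shift_gain = value_shift_gain,
    delta_epsilon = delta_epsilon, eta_gain = eta_gain,
    error_rate_off = error_rate_off, error_rate_on = error_rate_on,
    error_mix = error_mix / sum(error_mix),
    rt_params = list(meanlog_off = rt_meanlog, sdlog_off = rt_sdlog,
                     meanlog_on = rt_meanlog_on, sdlog_on = rt_sdlog_on)
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>  rho =", x$rho, " eta =", x$eta,
      " epsilon =", x$epsilon, " xi =", x$xi, "\n",
      " theta (juice/side/order) =", x$theta_juice, x$theta_side,
      x$theta_order, "\n",
      " stim:", x$stim_window,
      sprintf("(c = %g, d_eps = %g, eta_gain = %g)", x$value_shift_gain,
              x$delta_epsilon, x$eta_gain), "\n")
  invisible(x)
}

#' Design a counterbalanced sequential-offer session
#'
#' Builds the set of offer types and the shuffled trial list for one session
#' of the two-juice sequential-offer task. Offer types are chosen from the
#' supplied quantity levels so that their log quantity ratios straddle the
#' assumed indifference point log(rho) and most lie within the dynamic range
#' of the psychometric curve (at least 60% within |log(qB/(rho qA))| <=
#' 2/eta), so that the animal is expected to split choices for most values of
#' offer1. Extreme-ratio types anchor the two ends of the sigmoid. Offer
#' types with tied |log ratio| are kept or dropped together, which makes the
#' design symmetric under relabeling A <-> B when the configuration is.
#'
#' Each offer type appears in both presentation orders (AB: juice A first)
#' and both side assignments, counterbalanced up to one trial. Null offers
#' (0 drops) give forced-choice types; stimulation is assigned to half of the
#' non-forced trials (balanced within offer type), never to forced trials.
#'
#' @param qA_levels,qB_levels integer quantity levels available for each
#'   juice (include 0 to get forced-choice types).
#' @param rho assumed relative value used to center the design.
#' @param eta nominal sigmoid steepness used for the dynamic-range check.
#' @param n_trials total trials in the session (~400 in a typical session).
#' @param target_offer_types approximate number of non-forced offer types.
#' @param forced_fraction fraction of trials that are forced choices.
#' @param stim_fraction fraction of non-forced trials stimulated.
#' @param seed integer seed for the trial shuffle and stimulation assignment.
#' @return An object of class `choice_design` with elements `offer_types`
#'   (data frame of qA, qB, forced) and `trials` (one row per trial in
#'   presentation order).
#' @export
make_design <- function(qA_levels = 0:3, qB_levels = 0:6, rho = 2,
                        eta = 2.5, n_trials = 400, target_offer_types = 8,
                        forced_fraction = 0.25, stim_fraction = 0.5,
                        seed = 1) {
  stopifnot(rho > 0, eta > 0, n_trials >= 8, target_offer_types >= 4,
            forced_fraction >= 0, forced_fraction < 1,
            stim_fraction >= 0, stim_fraction <= 1)
  qA <- sort(unique(as.integer(qA_levels)))
  qB <- sort(unique(as.integer(qB_levels)))
  posA <- qA[qA >= 1L]; posB <- qB[qB >= 1L]
  if (length(posA) == 0L || length(posB) == 0L)
    abort_stimchoice("quantity levels must include positive quantities for both juices",
                     "stimchoice_design_error")

  cand <- expand.grid(qA = posA, qB = posB)
  cand$lr <- log(cand$qB / (rho * cand$qA))
  if (min(cand$lr) >= 0 || max(cand$lr) <= 0)
    abort_stimchoice(
      "offer quantity ranges cannot straddle the indifference point log(rho)",
      "stimchoice_design_error")

  # Select offer types the way the task's real offer sets are built: most
  # types spaced evenly across the psychometric dynamic range
  # |log(qB/(rho qA))| <= 2/eta, where the animal splits choices, plus
  # extreme-ratio anchors at both tails of the sigmoid. Whole tie groups are
  # kept so the selection is symmetric under A <-> B relabeling when the
  # configuration is.
  key <- round(cand$lr, 10)
  grp_keys <- sort(unique(key))
  inside <- grp_keys[abs(grp_keys) <= 2 / eta]
  outside <- grp_keys[abs(grp_keys) > 2 / eta]
  if (length(inside) == 0L)
    abort_stimchoice(
      "no offer type falls within the psychometric dynamic range (|log(qB/(rho qA))| <= 2/eta); refine quantity levels",
      "stimchoice_design_error")
  n_in <- min(ceiling(0.65 * target_offer_types), length(inside))
  pick <- inside[unique(round(seq(1, length(inside), length.out = n_in)))]
  # anchors outside the dynamic range, most extreme first, kept within a
  # member budget so that >= 60% of offer types stay inside; equal-|lr|
  # groups are added as a block to preserve A <-> B symmetry
  m_in <- sum(key %in% pick)
  budget <- floor(m_in * 2 / 3)
  n_grp_left <- target_offer_types - n_in
  used <- 0L
  for (a in sort(unique(abs(outside)), decreasing = TRUE)) {
    block <- outside[abs(outside) == a]
    m <- sum(key %in% block)
    if (length(block) <= n_grp_left && used + m <= budget) {
      pick <- c(pick, block)
      used <- used + m
      n_grp_left <- n_grp_left - length(block)
    }
    if (n_grp_left <= 0L) break
  }
  types <- cand[key %in% pick, , drop = FALSE]

  if (min(types$lr) >= 0 || max(types$lr) <= 0)
    abort_stimchoice("selected offer types do not straddle indifference",
                     "stimchoice_design_error")
  if (mean(abs(types$lr) <= 2 / eta) < 0.6)
    abort_stimchoice(
      "fewer than 60% of offer types fall within the psychometric dynamic range (|log(qB/(rho qA))| <= 2/eta); refine quantity levels",
      "stimchoice_design_error")

  offer_types <- data.frame(qA = types$qA, qB = types$qB,
                            forced = FALSE, row.names = NULL)
  has_nullA <- 0L %in% qA
  has_nullB <- 0L %in% qB
  forced_types <- data.frame(qA = integer(0), qB = integer(0))
  if (has_nullA) forced_types <- rbind(forced_types,
                                       data.frame(qA = 0L, qB = max(posB)))
  if (has_nullB) forced_types <- rbind(forced_types,
                                       data.frame(qA = max(posA), qB = 0L))
  if (nrow(forced_types))
    offer_types <- rbind(offer_types,
                         data.frame(qA = forced_types$qA, qB = forced_types$qB,
                                    forced = TRUE))

  n_forced <- if (nrow(forced_types)) round(forced_fraction * n_trials) else 0L
  n_free <- n_trials - n_forced
  nf_types <- which(!offer_types$forced)
  f_types <- which(offer_types$forced)
  counts <- integer(nrow(offer_types))
  counts[nf_types] <- split_even(n_free, length(nf_types))
  if (length(f_types)) counts[f_types] <- split_even(n_forced, length(f_types))

  # order/side combos cycled so that both marginals stay within +/- 1
  combo_order <- c("AB", "BA", "AB", "BA")
  combo_side  <- c("left", "right", "right", "left")
  type_of <- rep(seq_len(nrow(offer_types)), counts)
  combo_idx <- unlist(lapply(counts, function(k) ((seq_len(k) - 1L) %% 4L) + 1L),
                      use.names = FALSE)
  n_all <- length(type_of)
  stim <- integer(n_all)
  with_seed(seed, {
    if (stim_fraction > 0) {
      for (i in which(!offer_types$forced)) {
        at <- which(type_of == i)
        n_on <- round(stim_fraction * length(at))
        if (n_on > 0) stim[at[sample.int(length(at), n_on)]] <- 1L
      }
    }
    perm <- sample.int(n_all)
  })
  trials <- data.frame(
    q_A = offer_types$qA[type_of], q_B = offer_types$qB[type_of],
    order = combo_order[combo_idx], side_A = combo_side[combo_idx],
    forced = as.integer(offer_types$forced[type_of]), stim_on = stim,
    stringsAsFactors = FALSE)[perm, , drop = FALSE]
  rownames(trials) <- NULL

  structure(list(offer_types = offer_types, trials = trials,
                 n_trials = nrow(trials), rho_assumed = rho,
                 eta_nominal = eta, stim_fraction = stim_fraction,
                 forced_fraction = forced_fraction, seed = seed),
            class = "choice_design")
}

#' @export
print.choice_design <- function(x, ...) {
  cat("<choice_design> ", x$n_trials, "trials,",
      sum(!x$offer_types$forced), "offer types +",
      sum(x$offer_types$forced), "forced;",
      "rho_assumed =", x$rho_assumed, "\n")
  invisible(x)
}
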