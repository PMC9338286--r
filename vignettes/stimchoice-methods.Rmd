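---
title: "Models and methods behind stimchoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stimchoice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

stimchoice analyzes two-juice sequential-offer choice sessions in which weak
electrical microstimulation is interleaved with unstimulated trials, and
asks whether stimulation shifts offer values (relative-value and order-bias
changes) or degrades value comparison (increased choice variability). This
vignette is the package's own account of the models, the synthetic-data
world, and the numerical and design choices. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The choice models

On each trial the animal chooses between quantity $q_A$ of juice A (the
preferred juice) and $q_B$ of juice B, presented sequentially (AB trials:
A first) with randomized target sides. Choices are modeled with probit
regressions sharing the linear predictor

$$X = a_0 + a_1 \log(q_B/q_A) + a_2\, x_2, \qquad
  P(\text{choice B}) = \Phi(X),$$

where $x_2 \in \{-1, 0, +1\}$ is a difference of two indicator variables
and identifies the model:

| model | $x_2$ | bias ($a_2$) | positive sign means |
|---|---|---|---|
| order | $\delta_{AB} - \delta_{BA}$ | $\varepsilon$ | bias toward offer2 |
| side | $\delta_{A,\mathrm{right}} - \delta_{B,\mathrm{right}}$ | $\xi$ | left-target preference |
| hyst. juice | $\delta_{n-1,B} - \delta_{n-1,A}$ | $\theta_{\mathrm{juice}}$ | repeat previous juice |
| hyst. side | $\delta_{n-1,\mathrm{side}\,B} - \delta_{n-1,\mathrm{side}\,A}$ | $\theta_{\mathrm{side}}$ | repeat previous side |
| hyst. order | $\delta_{n-1,\mathrm{order}\,B} - \delta_{n-1,\mathrm{order}\,A}$ | $\theta_{\mathrm{order}}$ | repeat by presentation slot |

The sign convention for $\xi$ deserves the algebra: $x_2 = +1$ when juice A
is on the right, i.e. juice B is on the left; $\xi > 0$ then raises
$P(\text{choice B})$, so, other things equal, the animal tends to choose
the *left* target.

From the order-model coefficients the package derives the relative value
$\rho = \exp(-a_0/a_1)$ (the quantity ratio $q_B/q_A$ at indifference), the
sigmoid steepness $\eta = a_1$ (inversely related to choice variability),
and the order bias $\varepsilon = a_2$ ($\varepsilon < 0$ favors offer1).
Each bias model is fitted separately, one bias at a time, rather than
jointly — matching how the biases are reported and keeping every $a_2$
interpretable on the same scale.

Forced-choice trials (one offer of 0 drops) are excluded from every probit
fit because $\log(q_B/q_A)$ is undefined; they enter only the error-rate
and response-time summaries. Their *outcomes*, however, count as valid
previous choices for the hysteresis regressors: a forced choice is still a
choice the animal executed. Hysteresis regressors reference the most recent
trial with a valid choice, skipping error trials; trials before any valid
choice have an undefined indicator pair and are excluded from hysteresis
fits only.

## Fitting, convergence, separation

The probit log-likelihood is concave, so the maximizer is unique. The
package uses Fisher scoring with step-halving, computed entirely in log
space (`pnorm(log.p = TRUE)`), which keeps scores and weights finite far
into the tails without probability clipping. Convergence requires a
gradient norm $\le 10^{-6}$. Five restarts jittered around the first
solution guard against a pathological first run; the best log-likelihood
wins (by concavity they agree whenever they converge). A tiny scaled ridge
($10^{-10}$ of the mean information diagonal) keeps the Newton solve
defined under near-singular information.

Complete or quasi-complete separation (a linear predictor classifying every
choice perfectly) makes the MLE diverge. The original design sketch called
for a linear-programming feasibility check; no LP solver is available in
the package's dependency set, and one is not needed: under separation the
concave likelihood drives the optimizer toward a perfect classifier, so the
package flags separation when the *fitted* direction perfectly (strictly or
weakly) separates the observed choices. The flag can have no false
positives — the fitted direction itself exhibits the separator — and the
coefficient-norm guard (iteration stops once $\lVert b\rVert > 60$) bounds
the runtime of the diverging case. Separated fits report coefficients at
the stopping point, flagged unreliable.

Fits with fewer than 10 usable trials, a single distinct quantity ratio, or
only one observed choice raise typed errors rather than returning numbers.

## Per-session contrasts

Each session is split into stimOFF and stimON trials (forced trials are
never stimulated and fall in stimOFF; the stimulation window is constant
within a session). All five models are fitted per group;
$\Delta\rho, \Delta\eta, \Delta\varepsilon$ (from the order model) and the
four bias deltas are stimON minus stimOFF.

Value ranges use the session's stimOFF relative value:
$\Delta V_A = \rho_{\mathrm{OFF}} \cdot (\max q_A - \min q_A)$ in juice-B
units, $\Delta V_B = \max q_B - \min q_B$, with the minimum pinned at 0
drops whenever the session contains null offers (it always does when forced
trials are present). $\Delta V = \Delta V_A - \Delta V_B$. Using stimOFF
$\rho$ (rather than a pooled fit) keeps the range measure free of the
stimulation effect under test; the choice is recorded in the output
metadata. A consequence worth knowing: $\rho_{\mathrm{OFF}}$ noise enters
both $\Delta\rho$ and $\Delta V$, giving the null correlation
$r(\Delta\rho, \Delta V)$ a small negative bias that shrinks as the true
across-session spread of $\Delta V$ grows; with realistic session
heterogeneity it is negligible (the acceptance suite measures the null).

The error rate counts every trial that did not end in juice delivery —
initiation failures, center-fixation breaks, missed choices,
peripheral-fixation breaks — over all trials of the group; a variant
excludes initiation failures from both numerator and denominator. Mean
response time is taken over non-error trials.

## Population statistics

*Paired tests.* Two-tailed Wilcoxon signed-rank and paired t tests on the
session-by-session stimOFF/stimON values. The signed-rank test drops zero
differences (the classic treatment; Pratt's is the known alternative, and
the zero count is reported so readers can judge), uses exact enumeration of
the $2^n$ sign assignments for $n \le 25$ — implemented by subset-sum
convolution over doubled midranks, so ties are handled exactly — and a
normal approximation with continuity correction and tie-corrected variance
$\sum r_i^2/4$ above. The two-tailed p is
$\min(1,\, 2\min(P(W^+ \le w), P(W^+ \ge w)))$. All differences zero gives
$p = 1$ with a flag. The paired context implies signed-rank (not rank-sum)
semantics; that reading is the package default.

*Outliers.* A session is an outlier in a given analysis panel if it lies
more than 3 sample standard deviations from the mean on either axis,
computed once on the full set (no iteration). Removal is per panel and
never propagates back to the session store. A zero-SD axis removes nothing
and is flagged.

*Confidence ellipses.* The 90% ellipse is the Mahalanobis contour at radius
$\sqrt{\chi^2_{2,0.90}} \approx 2.146$ around the sample mean, axes along
the covariance eigenvectors.

*Effect sizes across conditions.* Three effect families over the 2
stimulation windows x 4 current-level labels ($\le$15, 25, 50, 125 uA —
labels only; effect magnitudes are configured per cell, never derived from
microamperes):

* *choice variability*: $\Delta cv = -\Delta\eta$, positive when
  stimulation flattens the sigmoid, regardless of window;
* *order bias*: $+\Delta\varepsilon$ for offer1 sessions,
  $-\Delta\varepsilon$ for offer2 sessions, so that a bias toward the
  *other* window's offer is positive;
* *range-dependent bias*: Pearson's $r(\Delta\rho, \Delta V)$ per current
  level, stimulation windows pooled, after the 3-SD outlier rule.

Rectification precedes averaging; condition means carry standard errors
$s/\sqrt{n}$ (the simplest defensible choice; no formula is prescribed);
each family is divided by its maximum condition mean so the largest effect
is exactly 1 (idempotent; skipped with a warning if no condition mean is
positive); significance is flagged at $p < 0.01$ (Wilcoxon for the first
two families, correlation test for the third). No multiple-testing
correction is applied, matching the analysis convention this package
follows.

## The synthetic-data world

The generator is first-class, tested code: every analysis stage is
verifiable without animal data. A session is ~400 trials; offered
quantities are integer drops; presentation order and target sides are
counterbalanced within offer type to within one trial; stimulation is
assigned to half of the non-forced trials, balanced within offer type;
forced trials are never stimulated.

*Offer types* are selected from the configured quantity levels the way the
task's real offer sets are built: about 65% of the target count spaced
evenly across the psychometric dynamic range
$|\log(q_B/(\rho q_A))| \le 2/\eta$ — where the animal splits choices — plus
extreme-ratio anchors at both tails, subject to a hard guarantee that at
least 60% of types stay inside the dynamic range and that the set straddles
indifference (violations raise a design error). Tie groups in
$|\log\text{-ratio}|$ are kept whole, which makes symmetric configurations
produce designs symmetric under relabeling A $\leftrightarrow$ B. An
earlier draft concentrated nearly all types at indifference; that starves
the slope of information (steepness recovery degrades noticeably), and the
even-coverage design — which is also what the real offer sets look like —
replaced it.

*Choices* are drawn from the same probit family the analysis fits, with
$a_1 = \eta$, $a_0 = -\eta\log\rho$, all bias terms included, and
hysteresis terms referencing the most recent valid choice (0 before one
exists). Stimulated trials receive three configurable effects: each offer
value gains `value_shift_gain` times that juice's value range (the
range-adaptation account of stimulation: firing-rate increases read out as
value increases proportional to the encoded range); the order bias shifts
by `delta_epsilon`; and when the session stimulates during offer2 — the
window in which the comparison is made — $\eta$ is multiplied by
`eta_gain`. With all three at their identity values the stimulated and
unstimulated processes are exchangeable.

*Errors and response times.* Error trials are drawn at 0.12 per stimulation
group (no rate is printed for the paradigm; 10–15% is typical for
fixation-controlled primate tasks, and the remark that excluding
initiation failures "markedly" reduces rates motivates weighting the
mixture toward them: 0.5/0.3/0.1/0.1 across no-initiation, center-fixation
break, no-choice, peripheral-fixation break). Response times are log-normal
with median 200 ms and sdlog 0.15, identical for stimON and stimOFF (no
stimulation effect on response times was observed in this paradigm). Both
are fixed defaults, not fitted quantities; only the error-rate and
response-time summaries consume them.

*Session heterogeneity.* A real dataset pairs different juices across
sessions, so the relative value (roughly 1–4 across juice pairs) and the
offered quantity ranges vary session to session. `simulate_experiment()`
exposes this through a per-session design grid. It matters for exactly one
analysis: the range-dependent bias is a correlation *across sessions*
between $\Delta\rho$ and $\Delta V$, which is degenerate (zero variance)
in a perfectly homogeneous world and underpowered in a nearly homogeneous
one. The acceptance suite's range-bias world therefore cycles through eight
juice pairings spanning relative values 1.2–4.0; the first draft used a
single fixed relative value, which both starved $\Delta V$ of variance and
let $\rho_{\mathrm{OFF}}$ estimation noise dominate the null correlation.

*What a green test does not establish.* The generator draws from the same
model family the analysis fits, so parameter-recovery results certify the
estimation machinery, not the model's adequacy for real behavior; real
sessions have drifting motivation, within-session value drift, omitted
covariates, and error processes correlated with difficulty, none of which
are emulated. Current levels are labels; nothing here models a
dose-response curve in microamperes.

## Seeds and reproducibility

Every stochastic entry point takes an explicit seed and restores the
caller's RNG state; identical (truth, design, seed) triples give
byte-identical trial tables. `run_pipeline()` writes a manifest (package
version, seed, config hash) from which any artifact can be regenerated;
there is no hidden state. Restart jitters inside the fitter use a seed
derived from the data size, so fits are deterministic functions of their
input.

## Known limitations

* Separation detection relies on the optimizer's diverging direction;
  adversarial near-separated datasets could in principle stop early without
  the flag (converged will be `FALSE`, which still marks the fit).
* The exact Wilcoxon switches to the normal approximation above $n = 25$;
  at $n = 26$–40 the approximation error is small but nonzero.
* $\Delta V$ uses the fitted stimOFF $\rho$, inheriting its estimation
  noise (see above); sessions whose order-model fit fails propagate `NA`
  deltas and are dropped from population analyses with a log line.
* The CLI (`inst/cli/stimchoice.R`) is a thin wrapper; programmatic use of
  the exported functions is the primary interface.
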