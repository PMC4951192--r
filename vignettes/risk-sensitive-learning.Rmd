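---
title: "Risk-sensitive reinforcement learning on the four-cue reward task: models, fitting, and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-sensitive reinforcement learning on the four-cue reward task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(rsrl)
```

## The task and why asymmetric learning predicts risk taking

The package implements the analysis pipeline for a trial-and-error learning
task with four visual cues: three paying a sure 0, 5 or 10 cents, and a
"risky" cue paying 0 or 10 cents with equal probability (expected value 5).
A session has 326 trials: 16 forced training trials (four per cue), 10
training choice trials (two of each of the five pair types), then 300 test
trials in two blocks of 150. Each test block contains 30 choice trials
pitting the risky cue against the equal-mean sure 5 cue — the trials that
measure risk preference — plus 20 risky-vs-0, 20 risky-vs-10, 15 0-vs-5 and
15 5-vs-10 choice trials, and 50 forced trials (14 risky, 12 per sure cue).
Risky payoffs are counterbalanced so that every epoch of eight deliveries
contains exactly four 0s and four 10s, pinning the experienced mean at 5.

Learners that update value estimates more strongly after positive than after
negative prediction errors overvalue variable options: the upswings count
more than the downswings. A learner with the opposite asymmetry undervalues
them and looks risk-averse — the pattern healthy adults typically show in
learned-choice tasks. The package exists to quantify that asymmetry from
choice data and to compare it between groups (a dystonia-patient-like group
with near-symmetric learning against a more risk-averse control-like group).

## The candidate models

All four models learn a value $V(c)$ per cue, initialized at 0, and choose
between offered cues $A$ and $B$ with the softmax

$$P(A) = \frac{e^{\beta V(A)}}{e^{\beta V(A)} + e^{\beta V(B)}},$$

where $\beta \ge 0$ (units 1/cent) sets choice determinism. With prediction
error $\delta = r - V(c)$ on the chosen cue, the updates are:

* **Asymmetric (risk-sensitive)**: $V \leftarrow V + \eta\,\delta\,(1+\kappa)$
  when $\delta > 0$ and $V \leftarrow V + \eta\,\delta\,(1-\kappa)$ when
  $\delta < 0$. Equivalent to separate learning rates
  $\eta^+ = \eta(1+\kappa)$, $\eta^- = \eta(1-\kappa)$. Negative $\kappa$
  produces risk aversion, $\kappa \approx 0$ risk neutrality.
* **Classical**: $V \leftarrow V + \eta(r - V)$ (the $\kappa = 0$ special
  case).
* **Nonlinear utility**: $V \leftarrow V + \eta(U(r) - V)$ with
  $U(0)=0$, $U(5)=5$, $U(10)=10a$; risk sensitivity via curvature $a$
  instead of asymmetric learning.
* **Win-stay-lose-shift**: the classical model with $\eta = 1$; only $\beta$
  is free.

A zero prediction error performs no update under every model. These
identities are enforced by tests as exact likelihood equalities:
asymmetric($\kappa=0$) $\equiv$ classical, classical($\eta=1$) $\equiv$
WSLS, utility($a=1$) $\equiv$ classical.

```{r}
dyt_mean <- rl_params("ASYMMETRIC", eta = 0.25, kappa = -0.05, beta = 0.68)
update_value(dyt_mean, v_old = 0, reward = 10)
choice_prob(beta = 0.93, v_a = 5, v_b = 0)
```

## Likelihood and fitting

`session_negloglik()` replays a session from zero values over all 326
trials. Every non-aborted trial updates the chosen cue's value from the
observed reward; every non-aborted choice trial — training choice trials
included, since participants learn from the first trial — contributes
$-\log p(\text{chosen})$; forced trials drive learning but contribute no
likelihood (only one response is scoreable), and aborted trials contribute
nothing at all. Probabilities are floored at $10^{-12}$ before the
logarithm so the objective stays finite at extreme $\beta$. The replay core
is compiled (Rcpp); the test suite checks it against a deliberately naive
pure-R replay to $10^{-10}$.

`fit_model()` minimizes this objective within bounds — $\eta \in [0,1]$,
$\kappa \in [-1,1]$ by default, $\beta \in [0,30]$, $a \in [0,3]$ — using
`nlminb`'s bounded quasi-Newton search from 5 starting points drawn
uniformly within the bounds, keeping the best restart. Two numerical points
were genuinely open:

* **Optimizer.** Box-constrained BFGS with finite-difference gradients
  stalls on this surface (it is badly scaled — $\beta$ spans 0–30 against
  $\eta$'s 0–1 — and locally rugged because the $\kappa$ factor switches at
  $\delta = 0$). The PORT quasi-Newton routine reaches the same optimum
  from most starting points; on typical simulated sessions the best and
  second-best of 5 restarts agree to well under 0.01 nats, which the suite
  asserts for 95% of sessions.
* **Bounds for $\kappa$.** The default $[-1, 1]$ keeps the effective
  learning rates $\eta(1 \pm \kappa)$ in $[0, 2\eta]$, so values remain
  convex combinations of observed outcomes and stay inside $[0, 10]$. A
  wider range up to $[-10, 10]$ can be requested (`kappa_limit`), with a
  warning: beyond $|\kappa| = 1$ one of the effective rates is negative and
  updates invert direction.

Convergence is declared at an absolute objective tolerance of $10^{-8}$.
The fit restart stream, simulation streams and cohort parameter draws use
separate derived seeds, so each stage is independently reproducible.

Identifiability caveat: a session of chance-level choices (true $\beta = 0$)
carries no information about the learning parameters. The optimum then sits
on a plateau — the fitted $\hat\eta$ collapses toward 0 and $\hat\beta$ is
arbitrary — so `recover_parameters()` flags sessions whose $\hat\beta$ lands
on a search bound as low-information rather than pretending the estimate is
meaningful.

## The synthetic cohort generator

No behavioral logs are distributed with the package, so cohorts are
simulated. `cohort_spec()` carries two presets with the fitted group
statistics of the study populations as parent moments of independent
truncated normals (truncation at the fitting bounds):

| group | $\eta$ | $\kappa$ | $\beta$ |
|---|---|---|---|
| DYT-like (patients) | 0.25 ± 0.19 | −0.05 ± 0.27 | 0.68 ± 0.37 |
| CTL-like (controls) | 0.14 ± 0.11 | −0.34 ± 0.27 | 0.93 ± 0.47 |

The printed values are sample moments of fitted parameters, not a
generative law, so no attempt is made to match the moments *after*
truncation; the parent moments are used as-is and documented here. All
agents in a cohort share one canonical schedule (trial order was fixed in
advance in the experiment), agents never abort (aborts were rare and
excluded), and per-agent seeds derive from the cohort seed.

An optional severity link maps the true asymmetry to a synthetic clinical
severity score, `severity = 10.2 + 30 * kappa + N(0, 8.5)`, truncated at 0.
The intercept and slope anchor zero severity at the control-like mean
asymmetry (−0.34), mirroring the observation that the severity regression
extrapolates to the control group's risk preference at zero symptoms, and
the noise was calibrated by brute-force search so the expected sample
correlation between severity and true $\kappa$ in a 13-agent cohort is
about 0.62–0.64, the magnitude the severity correlations reached in the
study.

What the generator does *not* emulate: parameter correlations across
individuals (the draws are independent), heavy-tailed or skewed individual
differences, within-session parameter drift, reaction times, side biases,
and aborted trials. Passing tests therefore show that the pipeline recovers
what this generative family produces — not that real participants obey the
model.

One emergent subtlety worth knowing: even a perfectly symmetric learner
($\kappa = 0$) ends slightly below indifference on risky-vs-5 trials
(about 0.45 at $\eta = 0.25$, $\beta = 1$). When the risky value drifts
low, the cue is chosen less and corrective updates arrive more slowly than
on the high side — the classic hot-stove asymmetry of choice-contingent
sampling. The 14 forced risky trials per block attenuate but do not remove
it. Group-level comparisons are unaffected (both groups experience it),
but $\kappa = 0$ should not be read as "exactly 50% risky choice".

## Model comparison and behavioral summaries

`nested_lrt()` compares the asymmetric against the classical model with the
likelihood-ratio statistic $2(\mathrm{NLL}_{red} - \mathrm{NLL}_{full})$ on
$\chi^2_1$. The suite checks its calibration end to end: fitting both
models to 500 classical-generated sessions rejects at $\alpha = 0.05$ in
3–8% of cases, and power against $|\kappa| = 0.5$ exceeds one half. The
asymmetric and utility models have equal parameter counts, so they are
compared directly via `per_trial_probability()`, the geometric-mean
probability per scoreable choice trial $\exp(-\mathrm{NLL}/n)$, with
choice trials only in $n$ (forced trials contribute likelihood 1 by
construction). WSLS is nested at the $\eta = 1$ boundary, where the
chi-square null is unreliable, so `model_selection_table()` reports that
comparison descriptively (log-likelihood differences) rather than as a
test.

`summarize_session()` computes the risky-choice proportion on risky-vs-5
test trials overall and in bins of 15 scoreable trials, accuracies on the
unambiguous pairs (sure pairs in bins of 15; risky-vs-0 and risky-vs-10 in
bins of 20, where "correct" means 10 over risky and risky over 0), the
accuracy on the first 5 test-phase sure-pair trials, and the probability
of choosing the risky cue conditioned on the outcome of the most recent
prior risky delivery. Conditioning counts forced deliveries as well as
chosen ones — every delivery updates the learned value, and the
forced/choice split is available separately via `conditional_by_context()`.
Trials before the first risky delivery are excluded from the conditional
tallies, and aborted trials are skipped everywhere (bins are defined over
scoreable trials). With 60 risky-vs-5 test trials the binning yields four
bins of 15; the bin count follows the trial counts.

Group statistics follow the study's nonparametric choices:
`group_compare()` runs the two-sided Mann-Whitney U test (exact enumeration
for combined $n \le 20$ without ties, tie-corrected normal approximation —
with the z statistic — otherwise) and the Wilcoxon signed-rank test for
paired win-vs-loss contrasts; `severity_correlation()` reports Pearson's r
with $n-2$ degrees of freedom.

```{r}
cohort <- simulate_cohort(cohort_spec("DYT", n_agents = 13, cohort_seed = 2))
beh <- summarize_cohort(cohort)
round(colMeans(beh$table[, c("overall_risky_prop", "p_risky_after_win",
                             "p_risky_after_loss")]), 3)
```

## Problem sizes and runtime choices

The simulation studies in the test suite and acceptance script use sizes
chosen to put Monte-Carlo error well below the effects being checked while
keeping a laptop-scale run: 1000 agents per preset for the early-learning
accuracy summaries, 10 replicate cohorts of 13 agents (the study's group
size) for parameter recovery, 500 null sessions for LRT calibration, and
1000 runs per grid point for the $\kappa$-monotonicity check. The compiled
likelihood makes a full 5-restart fit take a few tens of milliseconds, so
the entire suite runs in about a minute.

## Known limitations

* The generator's independent truncated normals reproduce the printed group
  moments but not the joint empirical distribution of individually fitted
  parameters; summaries that are nonlinear in the parameters (e.g. early
  accuracy averaged over agents) can differ by several percentage points
  from simulations that resample real individuals.
* Fits are per-session maximum likelihood; no hierarchical pooling.
* The task is single-step: no eligibility traces, no multi-step returns.
* No nuisance parameters for side bias or choice autocorrelation; a
  participant who always presses one side is unfittable by design and
  should be excluded upstream.
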