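---
title: "Modelling adaptation in adaptive-choice visual search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adaptation in adaptive-choice visual search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acvsadapt)
```

## The paradigm

In an adaptive-choice visual search (ACVS) task every display contains
two always-present targets — here a blue star and a blue pentagon among
14 black distractors on a 5 x 7 grid — and observers are free to report
either one. Because both targets are valid, the *choice* between them
indexes the observer's attentional control settings rather than task
demands. The distractor context changes systematically: a block is built
from 32-trial cycles consisting of a 3-trial *plateau* (all distractors
share one shape, making the other target a shape singleton), a 13-trial
*transition* in which one distractor per trial switches shape, the
opposite plateau, and a transition back. Searchers who exploit the
context should prefer the target whose shape matches the smaller
distractor subset, and should swing their preference across each
transition.

`build_cycle()` and `build_session()` construct these schedules
(practice blocks: one cycle plus a final plateau, 35 trials; main
blocks: three cycles plus a final plateau, 99 trials; the starting
plateau alternates between blocks), and `render_display()` realizes
individual trials as 16-item displays with target digits 1-4 and
distractor digits 5-8.

```{r}
cyc <- build_cycle("star")
head(cyc, 5)
nrow(build_session(2, 4))  # online-scale session
nrow(build_session(2, 8))  # lab-scale session
```

## The adaptation curve

Let $q(t) \in [0, 1]$ be the objective proportion of pentagon-shaped
distractors on trial $t$ of a block. The model for the probability of
choosing the star target is a chain of connected logistic segments,

$$
\mathrm{logit}\, P(\text{star at } t)
  = 2\,g\,\tau\,\bigl(\tilde q_\delta(t) - \tfrac12\bigr) - \beta,
\qquad
\tilde q_\delta(t) = q(t - \delta),
$$

with three interpretable parameters:

* **adaptation $\tau \ge 0$** — how strongly the choice log-odds track
  the signed shape imbalance of the distractor set. $\tau = 0$ is
  chance responding; as $\tau \to \infty$ the curve approaches a
  perfect discriminator that always selects the small-subset target.
* **shift $\delta$** (trials) — the lag with which control settings
  follow the environment. It is applied as a continuous horizontal
  translation of the objective trajectory, with linear interpolation
  between integer trial positions (estimates like 1.1 trials are
  meaningful) and flat extrapolation before a block starts.
* **bias $\beta$** — a ratio-independent preference for the pentagon
  shape, applied as a vertical shift on the log-odds scale.

Because $q(t)$ is piecewise linear — flat at 0/1 on plateaus, ramping
through the transitions — the curve consists of sigmoid rises and falls
joined by plateau segments at $\mathrm{logit}^{-1}(\pm g\tau - \beta)$,
exactly the qualitative shape the paradigm calls for.

### The gain constant

The steepness link $g$ between $\tau$ and the log-odds is a fixed
design constant, `gain = 6`. Two considerations pinned it down. First,
the interpretable anchors of the $\tau$ scale: with $g = 6$, $\tau = 1$
puts the plateau asymptote at $\mathrm{logit}^{-1}(6) = .9975$, i.e. a
curve that fully reaches the plateaus over the course of a transition,
while $\tau = 10$ behaves as an essentially perfect small-subset
discriminator. Second, conformance with published group-level fits of
this model family: evaluated at group posterior modes
$(\tau, \delta, \beta) = (0.092, 1.1, 0.17)$ the curve's plateau-phase
mean unique-target selection comes out at 58.9% / 66.8% for the two
starting-plateau conditions, and at $(0.12, 1.5, 0.13)$ at 63.1% /
69.0% — each within one percentage point of the reported 59/66% and
64/69%. `plateau_condition_means()` performs this evaluation, and
`scripts/acceptance.R` recomputes it from scratch.

```{r}
plateau_condition_means(adaptation_params(0.092, 1.1, 0.17))
```

A "starting-plateau condition" means: build a main block that opens
with a star (pentagon) plateau and average the predicted unique-target
probability over that block's star (pentagon) plateau trials — the
cycle-start plateaus plus the final plateau. Averaging over *all*
plateau trials of a block would mix both plateau types and cancel most
of the bias effect, which cannot produce the reported 7-point split;
the per-type reading reproduces it.

Observed choices enter through a Bernoulli likelihood
(`adaptation_loglik()`); probabilities are clipped to
$[10^{-12}, 1 - 10^{-12}]$ so that extreme parameters keep the
log-likelihood finite.

## Hierarchical inference

`fit_hierarchical()` embeds the curve in a hierarchical Bayesian model:
participant-level $\log \tau_s$, $\delta_s$, $\beta_s$ are normal
around group-level locations with group-level scales. $\tau$ is
parameterized on the log scale at the participant level, which both
enforces non-negativity and gives the sampler better geometry; the
reported group `tau` is $\exp(\mu_{\log\tau})$, the population median.

Priors are weakly informative and live in `hier_spec()` so they can be
overridden wholesale:

| parameter | prior | rationale |
|---|---|---|
| $\mu_{\log\tau}$ | Normal(-1, 2) | covers $\tau$ from ~0.01 to ~10, the interpretable range |
| $\mu_\delta$ | Normal(0, 3) trials | lags beyond a few trials are implausible but not excluded |
| $\mu_\beta$ | Normal(0, 1) | log-odds bias of $\pm 2$ is already extreme |
| scales | half-Normal(1) / (2) / (1) | vague, positive |

Sampling runs in JAGS through `rjags`. The continuous shift is handled
inside the sampler with `interp.lin` lookups into the padded objective
trajectory of each block type; $\delta$ is truncated to $\pm 9$ trials
(configurable) so lookups stay on the padded grid. Trials are
aggregated to binomial cells per participant x block-type x position,
which shrinks the graph about twofold without changing the likelihood.
Default settings are 4 chains x 1000 draws after 1000 adaptation
iterations; `hier_spec(full_scale = TRUE)` raises this to 20,000 draws
for publication-scale runs. Convergence is monitored with split-$\widehat R$
(each chain halved) and effective sample sizes; values of
$\widehat R > 1.01$ raise a warning carried in the result object rather
than failing the fit — under degenerate data (e.g. pure coin-flip
choosers) $\delta$ is unidentified and poor mixing on it is expected
and informative.

Posterior summaries follow the mode/HDI convention:
`posterior_mode()` is the argmax of a Gaussian-kernel density estimate
(Silverman's rule-of-thumb bandwidth, 512-point grid), and `hdi()` is
the shortest interval containing $\lceil 0.95\, n \rceil$ sorted draws.
`contrast()` summarises differences of posteriors (first vs. last
block, experiment A vs. B) by pairing draws by index.

## Preprocessing

Exclusion filters mirror the field's sequencing and use strict
inequalities, read literally from their usual phrasing:

* whole blocks with accuracy **< 75%** are removed first (block
  accuracy is computed before any trial-level filtering, since the
  filters' order of application to the same trial is otherwise
  ambiguous);
* trials whose reported digit is not among the two target digits are
  removed ("not contained in the display": with a 4-key pad and target
  digits in 1-4, distractor digits 5-8 are unreportable, so this means
  the two unused digits of 1-4);
* trials with RT **> 5000 ms** are removed (a 5000 ms trial is kept);
* for fixation analyses only, trials with RT **< 100 ms** are removed
  (a 100 ms trial is kept).

All filters are idempotent and attach machine-readable exclusion
reports.

## Response times

`mean_rt_by_phase()` averages RTs per participant over plateau
(P1-P3) and transition (T1-T13) trials; `best_compare()` is a
Kruschke-style BEST two-group comparison (Student-t observation model
per group, data-scaled vague priors on locations and scales,
shifted-exponential prior on the normality parameter), run in JAGS.
The plateau-vs-transition contrast treats the two per-participant mean
vectors as two groups, mirroring the two-sample framing customary for
this comparison even though the samples are paired; a paired analysis
is possible by differencing the phase means before calling
`best_compare()` against zero, but is not the default.

## Fixation analyses

Fixations are assigned to the display item with the nearest pixel
center (`assign_fixations()`); exact ties go to the lowest item index
and are flagged, and off-canvas fixations are assigned but flagged. The
central fixation mark is not an assignable item.

`normalized_shape_proportions()` divides the per-trial proportion of
(first/last/all) fixations on each shape class by the number of
displayed items of that class, so that a uniformly random fixation
yields 1/16 = .0625 for both classes regardless of the 15:1 subset
asymmetry on plateaus. `chosen_vs_nonchosen_plateau()` restricts to
plateau trials, splits them by whether the unique-shape target was
chosen, and reports per-participant-then-group means of first/last
fixation proportions and per-trial fixation counts on the chosen
vs. non-chosen shape; interval estimates on the differences come from
a seeded nonparametric bootstrap over participants (default 10,000
resamples), since no interval convention is standard for these tables.
`first_fixation_on_target_by_position()` tracks early guidance: the
proportion of first fixations landing on either blue target per cycle
position (chance 2/16).

## The synthetic-data generator

`simulate_study()` produces complete studies with known ground truth so
that every stage above is testable offline. It emulates: the
plateau/transition cycle structure at either experiment's scale (466 or
862 trials per participant); participant heterogeneity, drawn from the
same distributions the hierarchical model assumes (lognormal $\tau$,
normal $\delta$, $\beta$); Bernoulli choices from each participant's
adaptation curve; lognormal RTs with a plateau-to-transition offset
(defaults 950 ms and +60 ms, within the reported range for this task;
the lognormal is the package's choice for positivity and realistic
skew — the analyses model no RT distribution); wrong-digit reports,
timeouts (> 5000 ms) and anticipations (< 100 ms) at configurable
rates; planted chance-level participants whose blocks fail the
accuracy filter; and item-level fixation sequences.

The fixation agent is a deliberately simple test harness, not a
cognitive claim. In its `"stay"` mode the first fixation lands on a
target with probability `base + gain * |2q - 1|` (cycle-modulated early
guidance), intermediate fixations stay within the eventually chosen
shape subset with probability `p_stay`, and the last fixation is the
chosen target. Choices are drawn from the adaptation curve first and
the fixation sequence is generated conditional on the choice — the
reverse of an agent whose wanderings determine the choice — because
this keeps the Bernoulli observation model exactly correct for
parameter-recovery tests while still reproducing the qualitative
chosen-shape pattern (excess fixations on the chosen shape, larger for
last than for first fixations). Two null modes exist because two
different chance levels matter: `"uniform_item"` (every fixation
uniform over the 16 items; the 1/16 normalization chance) and
`"uniform_shape"` (every fixation picks a shape by fair coin; the null
for chosen-vs-non-chosen contrasts, which is *not* item-uniform on a
15:1 plateau).

All randomness flows from one root seed through named substreams
(cohort, choices, RTs, fixations), so cohorts and studies are exactly
reproducible.

What the generator does **not** emulate: sequential dependencies
(intertrial priming, post-error slowing), RT-accuracy coupling,
learning across blocks, saccade dynamics or fixation durations with
any empirical structure, and display-level salience effects. Passing
tests therefore show that the pipeline recovers what it assumes, not
that real data satisfy those assumptions.

## Orchestration

`run_pipeline()` chains simulate (or load from CSV) -> preprocess ->
fit -> RT comparison -> fixation analyses, writing CSV intermediates
and JSON summaries whose headers carry the seed and an md5 hash of the
configuration that produced them; any stage failure aborts with a
stage-tagged error. Configurations are plain YAML validated against a
known-key schema (`pipeline_config()`, `read_pipeline_config()`). The
numbered scripts under `analysis/` drive the same functions as a
narrative workflow.

## Problem sizes and numerical choices

The test suite and the analysis scripts run at desk scale, chosen as
the smallest sizes at which the statistical checks are meaningful:
parameter recovery uses 30 participants x 4 main blocks per replicate
across 20 replicates with 2 chains x 400-500 draws (coverage of 95%
HDIs is checked against a 17/20 binomial criterion per parameter);
BEST calibration uses 20 null replicates at n = 30 per group; fixation
checks use cohorts of 8-24 participants. Publication-scale runs use
`full_scale = TRUE`.

Other numerical conventions collected in one place: curve probabilities
clipped at $10^{-12}$; trajectory grids padded by `delta_bound + 2`
trials with flat extrapolation; KDE mode on a 512-point grid; HDI by
exhaustive sorted-window scan (exact, $O(n)$ after sorting);
equidistant fixation ties to the lowest item index; bootstrap and MCMC
seeds derived deterministically from user seeds.

## Known limitations

* The package's curve is the connected-sigmoid family above with a
  calibrated gain constant, and its priors are the weakly-informative
  defaults listed — both overridable where an exact match to an
  external specification is needed.
* Sampling uses JAGS (Gibbs/slice updates), not Hamiltonian NUTS;
  posteriors agree for this model class but mixing per draw differs,
  so draw counts are not comparable one-to-one.
* The BEST comparison ignores the pairing of plateau/transition means
  within participants (by design, for fidelity to the two-sample
  framing).
* Fitted values published for the original participants are only
  reproducible from the archived raw data, which this package does not
  download; its conformance checks rest on the deterministic curve
  evaluations and on synthetic-data recovery.
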