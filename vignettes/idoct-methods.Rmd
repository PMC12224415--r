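---
title: "Decomposing cognitive-task timecourses: model, simulator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing cognitive-task timecourses: model, simulator, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Computerised cognitive tasks record every stimulus and response, yet are
usually summarised by a single accuracy- or latency-based score. Such scores
conflate the cognitive process the task targets with visuo-motor speed,
device latency, and each person's speed–accuracy tradeoff. For
brain–behaviour association studies this conflation directly limits both the
strength and the interpretability of the associations.

This package implements an iterative decomposition of trial-level
timecourses (reaction time `RT` and binary correctness per trial, with a
condition label per trial — here, the word presented) into three families of
data-driven quantities:

* **item (trial) difficulty** `D(t)` in `[0, 1]`, and a presentee-scaled
  variant `DS(t)`;
* **participant ability** `A(i)` and **specific ability** `AS(i)` in
  `[0, 1]`, the latter computed after the visuo-motor component of `RT` has
  been removed;
* **visuo-motor delay** `DT(i)` in milliseconds.

## The model

Stage 1 defines, for a correct answer, per-trial performance
$$P(i,t) = \left(1 - \frac{RT(i,t)}{RT_{\max}}\right) D(t),$$
and $P = 0$ for a wrong answer, where $RT_{\max}$ is the maximum reaction
time over all trials and participants. Item difficulty is the complement of
mean performance over all presentations of the item,
$D(t) = \overline{1 - P(i,t)}$. Because $P$ depends on $D$ and $D$ on $P$,
the definition is circular; it is resolved as a fixed point, starting from
$D(t) = 1$ and iterating to convergence. Per item the update is affine,
$d \leftarrow 1 - c_t\, d$ with
$c_t = \overline{\mathrm{correct}\cdot(1 - RT/RT_{\max})} \in [0, 1)$, so
the fixed point $d^\* = 1/(1 + c_t)$ exists, is unique, and lies in
$(\tfrac12, 1]$ — a structural property worth noting: the data-driven
difficulty scale can never use the lower half of the unit interval, and an
item answered wrongly by everyone sits exactly at $D = 1$.

Stage 2 holds $D$ fixed and splits each reaction time into a cognitive
answer time and a visuo-motor delay, $RT = AT + DT$. The normalised answer
time of a trial is $ATN = (1 - A(i))\,D(t)$, the millisecond answer time
$AT = ATN\,(RT - DT_{\max}(i))$, where $DT_{\max}(i)$ is the participant's
minimum reaction time (their personal visuo-motor floor: on their fastest
trial the whole response is attributed to delay). Ability $A(i)$ is the mean
of $P(i,t)$ over the participant's trials. Abilities start at 1 and the
mutual recursion runs to a fixed point; updates are synchronous (all splits
from the previous abilities, then performance, then all abilities), which
makes the result independent of record order.

Stage 3 freezes the maximum answer time $AT_{\max}$ observed after stage 2
converges and scores
$$PA(i,t) = \left(1 - \frac{AT(i,t)}{AT_{\max}}\right) D(t)$$
for correct trials (0 otherwise). Specific ability $AS(i)$ is the mean of
$PA$; mean delay $DT(i)$ is the mean of the per-trial delays. $AS$ is the
package's headline ability score: it credits both accuracy and *cognitive*
speed while being insensitive to how slow a participant's motor response or
testing device is. In simulation this insensitivity is directly visible:
$AS$ correlates with the latent delay at roughly zero while the stage-2
ability $A$ is substantially contaminated by it.

Stage 4 corrects for adaptive sampling bias: hard items are shown mostly to
able participants, which depresses their apparent difficulty. The scaled
difficulty multiplies each item's $D$ by the mean $AS$ of the participants
who completed it, $DS(t) = D(t)\,\overline{AS}_{\text{presentees}(t)}$. Note
a documented oddity of this printed form: since the factor is at most 1,
$DS \le D$ item by item, so the *mean* of $DS$ cannot exceed the mean of
$D$; a renormalised variant that divides by the cohort-mean $AS$ (so that an
item seen by a representative slice of the cohort keeps $DS = D$) is
available via `idoct_control(ds_rescale = "cohort-mean")` but is not the
default.

### Numerical choices

* **Convergence** is declared when the mean absolute relative change of the
  iterated quantities falls below `tol` (default `1e-6`); caps are 1000
  iterations for the difficulty loop and 500 for the decomposition loop.
  Non-convergence is an error carrying the iteration history.
* **Damping.** The affine difficulty update can oscillate when reaction
  times approach zero ($c_t \to 1$ makes the map marginal). The solver
  watches for ten consecutive sign-alternating mean changes and then
  switches to a relaxation factor of 0.5. Damping changes the path, never
  the fixed point.
* **Exact conservation.** `AT + DT == RT` is maintained bit-exactly at
  every iteration: the rounded complement `RT - AT` can miss the identity
  by one unit in the last place, so the split is re-complemented until the
  identity closes (this moves `AT` by at most one ulp).
* **Degenerate inputs.** Items never answered correctly converge to
  `D = 1`; participants with all answers wrong get `A = AS = 0` with `DT`
  still defined; a participant with a single trial has `AT = 0`,
  `DT = RT`. A cohort in which *every* answer time is zero (e.g. one trial
  per participant) has `AT_max = 0` and cannot anchor the specific-ability
  scale; the fit stops with an instructive error.
* Bound comparisons use an absolute tolerance of `1e-12`.

### Frozen-parameter rescoring

`D`, `RT_max`, and `AT_max` are scaling constants of the model. To compare
scores across timepoints, follow-up sessions are scored with these three
frozen at their baseline values (`score_frozen()`), running only stages 2–3.
Rescoring the baseline data with its own frozen parameters reproduces the
baseline scores to floating-point noise, which the test suite asserts at
`1e-9`. Reliability is summarised descriptively (Pearson correlation,
Bland–Altman mean difference and ±1.96 SD limits); no longitudinal
modelling is attempted. Follow-up reaction times above the frozen `RT_max`
are an error by default (the choice is substantive, so it is surfaced);
`rt_overflow = "clip"` caps them with a count, and unknown items can
likewise be dropped with a count instead of erroring.

## The synthetic task

Real adaptive picture-vocabulary data from large biobanks is
access-restricted, so validation is by parameter recovery on a simulator
with known latent truth. The simulator emulates a four-alternative
forced-choice vocabulary task driven by an item-response-theory staircase:

* **Items.** A bank of 340 items (the task's word count) with true
  difficulties `b` evenly spaced on `[-3, 3]`, common discrimination
  `a = 1.5`, and guessing floor `c = 0.25` (four alternatives). The
  discrimination was chosen once so that the standard-error stop rule fires
  between the 20-trial minimum and the 30-trial cap, as the task design
  specifies; the real task's item parameters are not public.
* **Responses.** Correctness is Bernoulli with
  `P = c + (1 - c) logistic(a (θ - b))`. The reaction time is
  `rt = δ + τ softplus(κ (b - θ) + β) · exp(ε)`, `ε ~ N(0, σ²)`, with
  defaults `τ = 800` ms, `κ = 1`, `β = 1`, `σ = 0.3`: the cognitive
  component is positive, increases smoothly with the difficulty–ability
  gap, and carries multiplicative lognormal noise, so `rt > δ` always. The
  latent delay is `δ ~ lognormal(log 3000, 0.33)` (mean ≈ 3160 ms,
  matching the scale of visuo-motor delays observed in older adult
  cohorts); ability is `θ ~ N(0, 1)`.
* **Staircase.** Everyone starts at the easiest *labelled* item; after each
  response the ability estimate is the bounded maximum-likelihood estimate
  on `[-4, 4]` (all-correct/all-wrong histories pin to the bound with an
  infinite standard error, so the staircase keeps sampling extreme items);
  the next item is the unadministered one with labelled difficulty nearest
  the estimate. Sessions stop at `SE < 0.5` once 20 trials have run, or at
  30 trials.
* **Miscalibration.** The staircase believes the *labelled* difficulties.
  In `"ceiling"` mode the labels keep their full spread but the *true*
  difficulty saturates above a knee (default −0.5): the bank simply holds
  no genuinely harder material in the upper part of its scale. This knee
  places the end of the usable range below the ability-population median,
  the regime in which the task's own score becomes high and
  ceiling-compressed for the majority of the cohort — the published failure
  mode of the scale this simulator emulates. `"shuffled_top"` instead
  permutes the labels of the top quartile (bad ordering rather than
  compression). The task's own score (`ab`) is the terminal estimate mapped
  affinely onto `[0, 1]`; it is a qualitative analogue for comparisons, not
  a reproduction of any particular task's scoring.

What the simulator does **not** emulate: semantic word content, practice
and fatigue effects, trial-level dependence of delays (δ is constant within
a session), device heterogeneity, and missing data. Passing recovery tests
therefore show that the estimator extracts what this generative model puts
in — not that real cohort data satisfies the model.

### What recovery can and cannot show

At the study size used throughout (2000 participants, 340 items), mean
delay recovers the latent δ at Spearman ≈ 0.97 and item difficulty recovers
true `b` at ≈ 0.93 (items with ≥ 30 presentations). Specific ability
recovers θ at ≈ 0.5 on a *well-calibrated* bank — and this deserves an
honest explanation rather than a tuned simulation. A well-functioning
adaptive staircase deliberately equalises accuracy (and, with it, answer
time) across participants, so after adaptation the remaining between-person
signal lies mostly in *which* items were sampled. Because the data-driven
difficulty is structurally confined to `[0.5, 1]`, and a session holds only
20–30 Bernoulli trials, the unweighted mean that defines `AS` retains only
part of that signal; a likelihood-based estimate extracts ≈ 0.87 from the
same records. On a *miscalibrated* bank — the regime the method was built
for — adaptation fails, accuracy and speed vary widely between
participants, and `AS` recovers θ at ≈ 0.9 while the task's own
ceiling-compressed score loses rank information among the able majority.
In short: the decomposition adds the most where the task design helps the
least.

## Diagnostics

`difficulty_trajectories()` reproduces the standard validation view for
adaptive designs: participants binned into ten fixed ability groups
(`[0, 0.1), ..., [0.9, 1]` — left-closed, last bin closed, since only the
bin labels are conventional), and the mean difficulty of the items
presented at each trial position per bin. On a ceiling-miscalibrated bank
the top bins' labelled-difficulty trajectories reach their running maximum
early and stop increasing (`plateau_onset()`); empty bins are reported as
absent, not as zeros. `distribution_summary()` uses population-moment
conventions (`{0, 1}` has SD 0.5); shape moments of a constant vector are
flagged `NA` rather than invented.

## Feature selection

`select_features()` implements a deliberately simple linear association
machine, generic over any participants × features matrix: a seeded 75/25
train/held-out split; optional covariate (age) residualisation by ordinary
least squares; Spearman ranking of features against the target on training
rows only; a drop-lowest stepwise search over the nested model sequence
(all-but-one ranked feature down to the single top feature) under 5-fold
cross-validation with folds shared across all models; refit of the
highest-mean-validation-R² model on the full training set; and held-out
evaluation reported as-is (negative R² is not floored).

Design points the underlying description leaves open, decided here:

* **Tie-break** between steps with equal mean validation R²: fewer features
  win (parsimony).
* **Eta-squared** uses sequential (type-I) sums of squares in
  ranked-feature order, `SS_effect / SS_total`; values sum to the model R²
  and the decomposition is cross-checked against `stats::anova` in the
  tests. With correlated features, type-I attributions depend on order;
  the ranked order is the natural one for this pipeline and is stated in
  the output.
* **Significance flag** for the multivariate top-feature list is the
  per-coefficient t-test at `alpha = 0.05` (the effect-level F-test is the
  other defensible choice; the coefficient test matches how the feature
  lists are built downstream).
* **Constant features** (undefined correlation) are ranked last and
  flagged, never silently dropped, and never entered into the model search.
* **Leakage guards** are structural: the ranking function refuses a matrix
  flagged as holding held-out rows, and an adversarial test plants signal
  only in test rows and asserts it is not selected.

Null calibration: with a target independent of all features, the mean
held-out R² over 100 seeded replicates is slightly negative (about −0.04 at
n = 1000 with 50 features), as expected for honestly evaluated selection.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds (a master seed spawns
per-participant substreams in the simulator, so any single session can be
regenerated in isolation). The test suite and the acceptance script use
cohorts of 40–2000 participants, banks of 40–340 items, and feature
matrices of 1000 × 50 — sizes chosen so every documented property is
exercised at full fidelity on a single CPU. The same fits at biobank scale
(tens of thousands of participants) are a straightforward scale-up: both
iterative loops are linear in the number of trial records per iteration.

## Known limitations

* The specific-ability score is an unweighted mean, not an efficient
  estimator; under a perfectly calibrated adaptive design it recovers less
  of the latent ability than a likelihood-based score would (see above).
* The printed scaled-difficulty formula compresses the scale downward; the
  renormalised option exists but changes the scale's interpretation.
* `RT_max` and `AT_max` are cohort maxima and therefore sensitive to single
  extreme trials; `idoct_control(rt_max_quantile = )` offers a percentile
  cap, off by default to match the canonical definition.
* Repeated presentations of an item to the same participant are supported
  (each presentation event counts once in the difficulty mean), but the
  vocabulary-task design never exercises them, so that path is validated
  only by construction and unit test, not by simulation.
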