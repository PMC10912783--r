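---
title: "Methods: simulating and modeling the Sure-Bet-or-Gamble task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and modeling the Sure-Bet-or-Gamble task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`sborg`: the models, the synthetic-data generator, the sampler, and the
places where a design decision was genuinely open.

## The task

Each Sure-Bet-or-Gamble trial offers a certain reward on an integer dollar
grid ($1–$6) against a gamble of two equiprobable outcomes ($0–$6 each).
A response deadline is drawn per trial from a Poisson distribution with
mean 6 s; since the Poisson is discrete we treat deadlines as integer
seconds.  With probability 0.33 a trial is followed by a feeling prompt
answered on a −4..+4 integer slider.  Trials where one option is weakly
dominant (certain amount at least the high outcome, or at most the low
outcome) act as rationality controls; ties count as dominated because weak
dominance already makes one option rationally no worse.  The frequency of
dominated trials is not a published design constant, so it is a
configuration knob with default 0.2 — large enough that control-trial
behavior is measurable, small enough that conflict trials dominate the
session.  Option values are drawn uniformly on their integer grids (only
the ranges are published).  Sessions terminate after a fixed trial count
(default 208, the average session length); a trials-per-minute model of
the 30-minute window would add realism but no inferential content.
Left/right placement of the options is not modeled — it has no
computational consequence.

## The momentary-happiness model

The rating after trial $t$ is modeled as

$$\mathrm{Happiness}(t) = w_0
  + w_1 \sum_{j=1}^{t} \gamma^{t-j} CR_j
  + w_2 \sum_{j=1}^{t} \gamma^{t-j} EV_j
  + w_3 \sum_{j=1}^{t} \gamma^{t-j} RPE_j$$

with the zero-fill convention: on a certain-choice trial $CR_j$ is the
collected amount and $EV_j = RPE_j = 0$; on a gamble trial $EV_j$ is the
gamble's expected value, $RPE_j$ the obtained outcome minus that expected
value, and $CR_j = 0$.  The decay sums run over **all** preceding responded
trials, not just rated ones — the sums index every trial, while ratings
occur on only a third of them.  Timeout trials carry no choice or outcome
and are dropped from the history entirely.  Regressors enter in raw
dollars; the reported group-level weight magnitudes are consistent with
unscaled dollar regressors, and we keep that convention.

Parameters, units, defaults:

- `w0` — baseline feeling, z-units (typical fitted values near −1);
- `w1`, `w2` — z-units per decayed dollar of certain reward / chosen-gamble
  expected value (typical 0.1–0.25);
- `w3` — z-units per decayed dollar of reward prediction error (typical
  0.3–0.5);
- `gamma` — forgetting factor in $[0,1]$; 0 keeps only the current trial
  (typical fitted values 0.1–0.2, i.e. strong forgetting);
- `rating_noise_sd` — the Gaussian observation scale on z-scored ratings,
  a per-subject free parameter (the observation model is not published;
  a Gaussian with subject-level scale is the natural choice for
  standardized continuous ratings).

`decayed_sum()` evaluates the sums by the recursion
$S_t = \gamma S_{t-1} + x_t$ (via `stats::filter`), with $0^0 = 1$ so
$\gamma = 0$ returns the current value.  The test suite checks the
recursion against an explicit brute-force double loop to $10^{-12}$
relative error and verifies linearity of the prediction in
$(w_0, \dots, w_3)$ at fixed $\gamma$.

## Rating scales: one deliberate asymmetry

Inference operates on per-participant z-scored ratings (mean 0, sd 1,
denominator $n-1$); constant-rating sessions carry no usable variance and
are excluded with a warning.  The simulator, however, emits ratings
**directly on the z-scale** by default (`rating_scale = "z"`), because the
happiness model is defined on that scale.  Re-standardizing an
already-z-scale emission would shift $w_0$ by the sample mean of the
emitted ratings and rescale all weights, biasing parameter recovery; so
recovery analyses fit with `standardize = FALSE`, while real slider data
(or `rating_scale = "slider"`, which maps affinely at 2 slider units per
z-unit and rounds to the −4..+4 grid) takes the default standardizing
path.  This is why `fit_happiness_hier()` exposes `standardize` at all.

## Hierarchical fit

Within one condition cell, subject-level parameters are drawn around
group-level means: non-centered normal effects for $w_0..w_3$, and the
forgetting factor sampled on the unconstrained log-odds scale
($\gamma = \mathrm{logit}^{-1}(\cdot)$), which keeps every draw in $[0,1]$
without truncation and lets group heterogeneity act additively.  The
group-level $\gamma$ is reported as the logistic map of the group-level
unconstrained mean.  Cells are fit separately — the point of the analysis
is comparing independently estimated cells.

Priors (none are published, so these are declared, weakly informative on
the z-scale): group means $\mathcal N(0, 1)$ for the weights and
unconstrained $\gamma$; group standard deviations half-normal(0.2);
per-subject rating noise half-normal(1).  Prior-predictive $\gamma$ draws
span $(0,1)$ (checked in the tests).

Sampling is MCMC through JAGS with per-chain seeded Mersenne-Twister RNGs:
identical data, settings, and seed reproduce draws exactly.  Defaults are
4 chains, 1000 warmup and 1000 retained draws per chain after 500
adaptation steps; the analysis scripts and tests use 1–2 chains and
500-draw runs, which on this model (12–18 subjects, 208 trials) complete
in tens of seconds per cell on one CPU while keeping split-$\hat R$ of the
group-level parameters near 1.  Diagnostics report split-$\hat R$ and
effective sample size for every sampled quantity; fits with group-level
split-$\hat R > 1.05$ warn and should be re-run longer.  A
divergent-transition count is reported as `NA`: that diagnostic belongs to
Hamiltonian samplers and has no analogue in the Gibbs/slice family used
here.  The fit's correctness is cross-checked in the tests against a
direct per-subject maximum-likelihood optimizer (individual posterior
means within a few posterior standard deviations of the ML optimum under
wide priors) and against generative ground truth at design size (12
subjects × 208 trials): the core parameter-recovery property asserts group
means within 3 posterior standard deviations of truth.

## The gamble-choice model

Per participant, the decision to gamble is a logistic regression on the
gamble's expected value, the certain amount (raw dollars), and the
previous trial's rating (z-scale).  Fitting is maximum likelihood by
iteratively reweighted least squares (`glm`, log-likelihood tolerance
$10^{-8}$).  A magnitude guard ($|\beta| > 20$) raises a separation flag
rather than silently shrinking — transparency over convenience at the
~65-row fits the `rated_only` mode produces.

The previous-rating regressor has two published descriptions: only trials
preceded by a rating were used, and ratings were "actual or imputed".
Both are implemented: `rated_only` (default) keeps responded trials whose
immediately preceding trial was rated; `locf` carries the most recent
rating forward over all responded trials after the first rating.  Neither
is asserted to be the original procedure.  In practice `rated_only` at
design size leaves roughly a third of trials per fit and, with strong true
effects, occasionally produces quasi-separated per-subject estimates that
inflate group means; `locf` triples the rows and is markedly more stable.
The analysis workflow reports both.

Group summaries are the mean per-subject coefficient with a one-sample
t-test against zero and a $t$-based 95% CI ($n-1$ degrees of freedom);
zero-variance coefficient sets are flagged with an undefined $t$.

## Posterior comparisons

- **HDI**: the narrowest contiguous window of the sorted draws containing
  $\lceil \text{mass} \cdot n \rceil$ of them, exhaustively-searchable and
  tested against an all-windows oracle.  Ties between equally narrow
  windows resolve to the left-most; multimodal posteriors still yield a
  single interval (a documented limitation — the group-level posteriors
  here are unimodal in practice).
- **Difference distributions** pair draws index-wise after thinning the
  longer vector to evenly spaced draws; the cells are fitted
  independently, so any pairing is valid and index pairing is
  reproducible.  Sign conventions: ICD − non-ICD, On − Off.
- **Posterior Cohen's d** uses the unpooled-mean/pooled-variance form
  $(\bar A - \bar B)/\sqrt{(s_A^2 + s_B^2)/2}$.  This convention is pinned
  down by reconstruction: applying it to the published posterior means and
  95% HDIs (normal approximation, sd = width/3.92) reproduces the
  published off-medication effect sizes to within 1%
  (`cohens_d_from_summary()`, verified in the acceptance tests).
- **Credible fractions** count difference draws per side of zero, splitting
  exact zeros evenly; a difference is called credible past 97.5% on either
  side.  No multiplicity adjustment is applied across the five parameters.

## The synthetic cohort: what it emulates, what it does not

The generator reproduces the study's design conditions: 18 ICD + 12
non-ICD subjects, two visits, 208 trials per session, 33% rating prompts,
~3% timeouts, choices from the logistic rule (previous emitted rating
carried forward, 0 before the first), ratings from the happiness model
plus Gaussian noise (sd 0.5 z-units by default).  Group-level generative
means are the published group estimates per cell; the previous-rating
choice weight defaults to 0 since it was not significant in any cell.
Individual-level dispersions are nowhere published, so the defaults (0.05
for happiness weights, 0.5 for unconstrained $\gamma$, 0.3 for choice
betas) are plausible-scatter choices, fixed once — not calibrated to any
test outcome.

What the simulator does **not** emulate: reaction times and their coupling
to deadlines; learning or drift across a session; medication
pharmacokinetics; slider-use idiosyncrasies (anchoring, discreteness
beyond rounding); non-Gaussian rating noise; any dependence of timeouts on
trial difficulty.  Passing recovery tests therefore shows the pipeline is
self-consistent and estimable at design size — not that real patient data
meet the model's assumptions.  Model-fit r² on simulated cohorts runs
higher than is typical for patient data because simulated ratings are
generated by the fitted model family itself.

## Numerical and degenerate-input policy

- All randomness flows from explicit seeds; sub-seeds are drawn from a
  seeded stream, and every seeded helper restores the caller's RNG state.
  The pipeline refuses configs without a seed, and identical config + seed
  reproduce byte-identical artifacts (tested).
- Paired gamble-rate contrasts with all-zero differences return p = 1 (the
  signed-rank statistic is undefined there; "no evidence of a shift" is
  the only defensible summary).  Within-group on-vs-off contrasts are
  paired by subject and use the signed-rank test; between-group contrasts
  use the rank-sum test, which small-$n$ tests verify against exact
  permutation enumeration.
- `fit_r2()` is a squared Pearson correlation: affine-invariant,
  sign-blind, and undefined (an error) under zero variance.  Group-level
  r² pools all rated trials across a cell's subjects; per-trial-bin
  averaging is a plausible alternative aggregation, but pooling is the
  declared choice.
- Sessions with constant ratings or fewer than 5 usable ratings are
  excluded from fitting with a logged warning, never silently.

## Problem sizes

Unit tests run on cohorts of 2–4 subjects with 60–150 trials and reduced
chains; the recovery and determinism checks use one cell at the full
design size (12 subjects × 208 trials) with 2 × 500 retained draws, and
Monte-Carlo law checks use $10^4$–$10^5$ draws.  These sizes were chosen
as the smallest at which each property is sharply testable.

## Known limitations

- The HDI is single-interval by construction.
- Split-$\hat R$ near 1 at 2 × 500 draws still leaves effective sample
  sizes of a few dozen for the slowest-mixing group parameters; production
  analyses should use the 4 × 1000 defaults.
- The per-participant-fit + group t-test reading of the choice analysis is
  one of two plausible readings (the other being a mixed-effects logistic
  model); it is the one matching the published estimate/CI/t/p table
  structure, and the hierarchical-logistic variant is out of scope.
- Group labels and medication states are taken as given; nothing in the
  package models diagnosis or dosing.
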