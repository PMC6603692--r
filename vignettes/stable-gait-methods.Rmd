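---
title: "Methods: density thresholds, quantile-change stability, and crossover validation for wearable running gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: density thresholds, quantile-change stability, and crossover validation for wearable running gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitstab)
```

## The problem and the model

A waist-worn IMU reports, once per five strides, six biomechanical
variables: cadence (steps/min), vertical oscillation (cm), ground contact
time (ms), braking (m/s), pelvic drop (deg) and pelvic rotation (deg). With
repeated real-world runs, a subject-specific "stable" gait pattern can be
defined distributionally: records from one runner, in one elevation
condition, are modelled as draws from a (multivariate) normal distribution,

$$x \sim \mathcal N_d(\mu, \Sigma), \qquad d \in \{1, 6\},$$

fitted by the sample mean and the $n-1$-denominator sample covariance. The
model rests on three assumptions worth keeping in view: (i) within-condition
records are approximately normal around a runner-specific mean, (ii)
run-to-run differences act mainly as additive mean shifts, and (iii)
elevation affects gait through condition-specific offsets. None is exactly
true of real running, but together they make "has the fitted distribution
stopped moving?" a precise question.

Three derived statistics carry the analysis.

**Epsilon.** The density threshold $\varepsilon$ is set so that at least 95%
of the training records have fitted density $f(x) \ge \varepsilon$. A test
record is *similar* iff $f(x) \ge \varepsilon$ (ties inclusive, following
the defining inequality). The percentage of similar test records and the
count outside the contour (`n_outside`) are the similarity outcomes.

**Quantile pair and stability.** For training sets pooled over the first
$N$ runs, the fitted distribution is summarised by its 2.5/97.5 quantile
pair. The stability point is the smallest $N$ such that adding run $N+1$
changes both quantiles by less than 5% (relative change,
$100\,|q_{N+1}-q_N|/|q_N|$). Cohort tables report the mean, SD and maximum
across runners; the maximum is the operational "how many runs do you need".

**Crossover.** With five randomly selected training runs and two test runs
per runner, a model trained on one condition is tested against every
condition; `n_outside` per (train, test) cell is correlated across runners
with the original within-condition analysis at the five-run point, and
banded poor / good / very good / excellent at 0.60 / 0.80 / 0.95.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| warmup discard | 1 | km | removes the unrepresentative first kilometre |
| distance cap | 10 | km | guards against fatigue effects late in long runs |
| smoothing window | 10 | s | moving average on GPS speed and altitude |
| speed gate | 1.8 | m/s | drops walking/pauses; applied to smoothed speed |
| window length | 100 | m | elevation windows over retained running distance |
| level band | ±2 | % grade | window condition bins; uphill +3..+15, downhill −3..−15 |
| coverage | 0.95 | — | training mass at or above epsilon |
| stability threshold | 5 | % | quantile-change rule |
| crossover split | 5 + 2 | runs | training/test designation |

All are arguments of the respective functions and of `pipeline_config()`;
the defaults are the study conditions the package targets.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws runner profiles from a population (means,
runner-to-runner spread, a shared within-run correlation structure with
runner-specific SD scales), then per run: a 1 Hz GPS stream over the
runner's route with speed noise and occasional sub-1.8 m/s pauses, and an
IMU stream whose record interval is recomputed from each record's own
cadence draw (a stride is two steps, so five strides at cadence $c$
steps/min take $600/c$ seconds). Each run receives one additive mean-shift
draw (`between_run_sd`); each record adds the condition effect of the true
route grade beneath it, so ground-truth labels exist for segmentation tests.

Key default choices, made once as the package's study conditions:

- **Population values** (means 164 spm, 8.5 cm, 255 ms, 0.28 m/s, 8.0°,
  10.0°; within-run SDs 3, 0.6, 12, 0.05, 1.2, 1.8; between-run SDs about
  half the within-run SDs) are physiologic for recreational distance runners
  at ≈ 2.4 m/s. They are stated defaults, not estimates from any dataset.
- **Condition effects** shift uphill running toward higher cadence, shorter
  bounce and longer contact, and downhill running toward larger braking
  (+0.08 m/s on average); each runner receives the population effect plus a
  runner-specific Gaussian deviation (`effect_sd`), reflecting individual
  grade response.
- **Routes are runner-specific** (`random_route()`): total length uniform on
  12–16 km, terrain shares Dirichlet-distributed around
  level/up/down/gap = 0.37/0.28/0.28/0.07 with concentration 6, segment
  lengths 300–800 m, grades uniform within each condition bin. Uncontrolled
  routes are essential: they give runners stably different per-condition
  data volumes, which is what makes count-valued crossover outcomes
  correlate strongly across runners in same-condition analyses. A shared
  fixed route can be forced via `cohort_config(route = ...)`.

What the generator does **not** emulate: raw accelerometry and the vendor's
on-board gait-event detection (the six variables are generated directly);
non-normal features of real gait data (skewness, heavy tails, drift within
a run, autocorrelation between consecutive records); GPS measurement error
in position/altitude; surface, footwear, weather and fatigue effects.
Passing tests therefore demonstrate that the pipeline's statistics behave
as designed *under the model's own assumptions*; they do not certify
behaviour on real, messier data.

## Numerical choices

- **Epsilon estimator.** The empirical 5th percentile of training densities
  with the linear-interpolation definition (R's type-7 quantile). At small
  $n$ the interpolated percentile can leave fewer than 95% of training
  points at or above it (at $n = 10$, only 9/10); since the threshold is
  *defined* by its coverage guarantee, epsilon then steps down to the
  largest order statistic restoring coverage ≥ 95%.
- **Singular or ill-conditioned covariances** (condition number above
  $10^{12}$, or $n \le d$) receive a ridge: a small multiple of the mean
  diagonal, grown by decades until the Cholesky factorization succeeds. The
  added magnitude is stored on the fitted object and signalled.
- **Multivariate quantile pair.** "2.5/97.5 quantiles" of a multivariate
  density has no canonical definition. The package uses closed-form
  density-height quantiles: since the Mahalanobis form is $\chi^2_d$, the
  $p$-quantile of the fitted pdf height is
  $(2\pi)^{-d/2}|\Sigma|^{-1/2}\exp(-\chi^2_d(1-p)/2)$. This is
  dimension-consistent and deterministic, and the quantile functional is a
  pluggable argument of `stability_point()` for sensitivity analysis. The
  univariate branch uses conventional variable-space quantiles
  $\mu \pm 1.959964\,\sigma$, the natural reading for $d = 1$.
- **Near-zero quantiles.** Relative change explodes when a previous
  quantile sits at zero (possible for variables crossing zero). When
  $|q_{\text{prev}}| < 10^{-12}$ the delta switches to an absolute scale —
  the fitted SD for univariate models, the previous $q_{\text{high}}$ for
  density heights — and the switch is flagged in the output.
- **Windows** are half-open $[100w, 100(w+1))$ in *retained* running
  distance: metres covered during sub-gate seconds contribute no length, so
  every window is exactly 100 m of active running and every contiguous
  same-condition section is ≥ 100 m by construction. The processing order is
  trim → smooth → speed-gate → window → classify; grades in the (2, 3]%
  magnitude gap or beyond 15% are `unclassified` and count only toward the
  mixed condition. Grade-bin endpoints are closed as printed
  (|g| ≤ 2; ±3…±15 inclusive).
- **IMU–GPS synchronization** assumes a shared clock; each record's distance
  is the linear interpolation of GPS cumulative distance at the record
  timestamp — the simplest contract consistent with 1 Hz GPS.
- **Run ordering** for the stability criterion is chronological ("adding a
  new run" accumulates sessions in time); `stability_scan(mode = "permuted")`
  averages over seeded random orderings as a sensitivity analysis. The rule
  is first-crossing; a stricter sustained mode (every later addition also
  under threshold) is available via `sustained = TRUE`. The reported value
  is $N$, the training-set size before the first sub-threshold addition, so
  a single run can constitute stability — consistent with cohort means
  below 2.
- **Split accounting.** The published seven-run pair table
  (49, 126, 175, 140, 63, 14, 0) equals $\binom{7}{N}(7-N+1)$ for $N < 7$,
  not the $\binom{7}{N}(7-N)$ implied by counting each left-out run once. It
  is reproduced exactly by treating, for each unique training set, each
  left-out run *and the pooled complement* as testing datasets.
  `split_counts()` defaults to that accounting;
  `split_counts(pooled_complement = FALSE)` and
  `similarity_sweep(pooled_complement = ...)` expose the strict
  leave-one-out count (441 pairs for seven runs).
- **Crossover reference.** The "original analysis at the five-run point" is
  computed as the mean `n_outside` over all $\binom{7}{5}$ leave-out splits
  with five training runs, per runner and condition; off-diagonal cells are
  correlated against the reference of the *test* condition (pluggable via
  `reference_condition`).
- The similarity sweep is descriptive; the stability decision uses only the
  quantile-change rule.

## Known limitations

- **Multivariate stability at $N = 1$ is noise-limited.** The density-height
  quantiles scale with $|\Sigma|^{-1/2}$, so their relative change under
  pure sampling noise is roughly $\tfrac12\sqrt{d/n}$ per addition — about
  3.7% for $d = 6$ at $n \approx 1100$ records/run, straddling the 5% rule.
  Even with zero between-run variance, the multivariate stability point is
  therefore 1 only for the typical runner, not all runners; the univariate
  criterion, dominated by the mean, settles immediately. This is a property
  of the quantile functional, not an implementation artifact.
- The normality assumption makes the epsilon contour an ellipsoid; real
  gait data with skewed or multimodal structure would mis-calibrate
  coverage.
- Windows containing a speed-gate splice join altitude across the removed
  span, which can produce an unrepresentative grade for that single window.
- The generator's condition labels are exact at generation time; after
  windowing, records in windows straddling terrain transitions are
  legitimately assigned the window's (mixed-terrain) grade condition, so
  ground-truth agreement is checked on uniform interior windows.

## Problem sizes used by the test suite

The suite exercises reduced cohorts chosen to keep Monte-Carlo error well
inside the asserted tolerances: 2–3 runners × 7 runs for segmentation and
identity checks; 6–8 runners × 7 runs for the zero-variance and
monotonicity properties; a full study-scale 35 runners × 7 runs for the
crossover correlation structure; $10^4$–$4\times10^5$ draws for the
distributional oracles. The acceptance script fits 10,000 six-dimensional
records drawn from the default population's within-run normal.
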