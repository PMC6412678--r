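---
title: "Methods: conformal prediction for e-nose sensor arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformal prediction for e-nose sensor arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enoseCP)
```

## The problem

An electronic nose is an array of partially selective metal-oxide
(MOS) gas sensors. No single sensor identifies a volatile sample, but
the joint pattern of all channels fingerprints it, which makes e-noses
attractive for cheap, fast authentication of complex odours such as
powdered herbal medicines. A plain classifier on e-nose features gives
a label but no per-prediction reliability statement, which matters when
the decision has economic consequences (high-value herbs are routinely
adulterated). Conformal prediction adds exactly that: for every
candidate label it produces a p-value with a finite-sample coverage
guarantee, from which set-valued predictions, confidence and
credibility follow.

`enoseCP` implements the full pipeline: simulation of raw sensor
recordings, baseline normalisation, transient feature extraction,
inductive (ICP) and bootstrap-aggregated (ACP) conformal classification
over SVM or random-forest scorers, and the standard evaluation battery
(validity curves, efficiency curves, forced-prediction accuracy,
confidence/credibility summaries).

## Signal model and preprocessing

A measurement cycle has three phases: a pre-injection baseline window,
a reaction window in which the sample gas reaches the sensors, and a
cleaning window under reference air. `timing_config()` defaults to
20 s / 200 s / 120 s, a common protocol for MOS arrays. Sensors read
out through a voltage divider; `voltage_to_resistance()` applies
`Rs = RL * (Vc - V) / V`, isolated in one function because divider
constants vary between instruments (inputs already in resistance skip
it).

Baseline normalisation converts each trace to the dimensionless
relative response

$$R(t) = \frac{R_\text{sample}(t) - R_\text{baseline}}{R_\text{baseline}},$$

with the per-sensor baseline taken as the mean over the *entire*
pre-injection window declared in the timing (the least arbitrary
reading of "the first N seconds of data"). This makes features
invariant to per-sensor gain and baseline level; the package applies no
further drift compensation.

## Features

Five features per sensor, in fixed sensor-major order
(`S1_rmax, S1_rint, S1_ema_a0.005, S1_ema_a0.05, S1_ema_a0.5, S2_rmax, ...`),
so a 16-sensor array gives an 80-dimensional vector:

* `rmax` — maximum absolute relative response, the saturation level;
* `rint` — trapezoid-rule integral of R over the recording, the
  cumulative exposure response;
* `ema_a*` — maximum absolute exponential moving average of the first
  difference, `y(k) = (1 - a) y(k-1) + a (R(k) - R(k-1))`, at smoothing
  factors a = 0.005, 0.05, 0.5 — three views of the injection
  transient's slope at different time scales.

Three numerical choices were genuinely open and are resolved as
follows. First, the EMA recurrence is read as the EMA *of the first
difference*; the alternative reading `a*R(k) - R(k-1)` is not a moving
average of anything (it is dimensionally incoherent as a smoother) and
is rejected. Second, the recurrence starts at `y(0) = 0`, the standard
EMA initialisation, consistent with a flat pre-injection derivative.
Third, the recurrence runs over the full recorded series by default; a
fixed-length index range only makes sense for one specific sampling
rate, whereas the feature is a maximum dominated by the injection
transient either way. An optional `decimate_to` flag subsamples first
for users who want rate-independent EMA values. Likewise the integral
is taken over the full window by default, with
`integration_window = "reaction"` available, because the integration
horizon is a protocol choice, not a property of the data.

All five features are positively homogeneous of degree 1 in R, which
the tests exploit as an invariant.

## Conformal prediction

For a calibration set of nonconformity scores
$\alpha_{1}, \dots, \alpha_{n}$ and a test object with score
$\alpha^c$ under candidate label $c$, the p-value is

$$p_c = \frac{\#\{j : \alpha_j \ge \alpha^c\} + 1}{n + 1},$$

ties counted inclusively. The prediction region at significance level
$\varepsilon$ is $\Gamma^\varepsilon = \{c : p_c > \varepsilon\}$
(strict), forced prediction is the argmax-p label, confidence is one
minus the second-highest p-value and credibility is the highest
p-value.

Design choices where the method family leaves room:

* **Nonconformity measure.** $\alpha = 1 - \hat P(c \mid x)$, with
  Platt-calibrated probabilities for the RBF-SVM (C = 6000,
  gamma = 0.001) and vote fractions for the random forest (500 trees).
  This is the standard classification measure and works uniformly
  across both scorers; it lives behind `nonconformity()` so margin
  alternatives can be added.
* **ICP split.** Stratified 2/3 proper-training / 1/3 calibration by
  default, configurable via `calib_fraction`; the proportion materially
  affects efficiency, hence it is exposed.
* **ACP resampling.** Each of the K (default 5) folds draws a
  stratified bootstrap of the full training size — per class, `n_c`
  draws with replacement — keeping duplicates for fitting, and uses the
  out-of-bag examples (expected fraction $(1 - 1/n_c)^{n_c} \approx
  0.37$) as that fold's calibration set. Folds with an empty
  out-of-bag set or a missing class are redrawn up to a bounded retry
  count. The ACP p-value is the arithmetic mean of the K fold
  p-values.
* **Ties and smoothing.** P-values are unsmoothed (deterministic,
  conservative) by default; `smoothed = TRUE` randomises ties for
  exact-validity experiments.
* **Standardization.** Features are z-scored (fit on the training
  portion only) before the SVM, whose fixed kernel width assumes
  comparable scales; off for the scale-invariant forest. Both are
  overridable.
* **Seeding.** One user seed drives everything; per-fold and
  per-specimen sub-seeds are derived with a fixed affine scheme
  (`derive_seed`), so ICP splits, ACP bootstraps and CV folds are
  bit-reproducible.

### The p-value floor

Every ICP p-value is at least $1/(n+1)$, and by exchangeability a test
object's true-label score exceeds *all* calibration scores with exactly
that probability. When it does, every label sits at the floor and
forced prediction degenerates to the tie rule (lowest label index,
logged). With small, overconfident calibration sets — a random forest
assigning probability 1 to nearly all out-of-bag points is the typical
case — this is the dominant error mode even on perfectly separable
data. Aggregation largely removes it, since a simultaneous floor tie in
all K folds is much rarer; this is visible in the test suite, where the
aggregated predictor reaches exact accuracy 1 on a widely separated
synthetic dataset while a single inductive split does not.

## What the generator emulates — and what it does not

`make_signatures()` + `simulate_recording()` produce class-specific
response curves: per-sensor baseline times
$(1 + A_\text{eff}(1 - e^{-t/\tau_r}))$ during reaction, first-order
decay with $\tau_d$ during cleaning, plus additive Gaussian noise and
a per-recording linear drift. First-order kinetics match the
saturating rise and decay seen in MOS responses with a minimal
parameter count. Within-class variability is a mean-one lognormal
factor on the amplitudes (multiplicative, keeps response signs), with
coefficient of variation 0.08 by default. Class amplitude rows are a
common base vector plus Gaussian offsets scaled by `separation`, so
between-class distance is exactly proportional to that knob and
`separation = 0` is an exchangeable null.

`simulate_feature_table()` bypasses the signal layer: class-conditional
spherical Gaussians in feature space, class means at
`separation` × standard-normal directions, unit within-class noise. Its
default `separation = 0.3` was chosen once so that, at the study scale
of 10 classes × 50 specimens × 80 features, forced-prediction accuracy
lands in the moderate-overlap band (roughly 65–80 %) where comparisons
between predictors are informative; it is a free knob, not calibrated
to any real instrument.

Neither generator models real sensor chemistry: no humidity or
temperature effects, no cross-cycle memory, no heteroscedastic or
correlated noise, no class structure beyond mean shifts. Passing tests
therefore demonstrate the *statistical machinery* — validity under
exchangeability, aggregation identities, feature correctness — not
performance on real botanical headspace data.

## Evaluation protocol and problem sizes

`cross_validate()` uses seeded stratified k-fold CV (per-class fold
sizes differ by at most 1); each fold's conformal model is fit entirely
inside the training portion. `calibration_curve()` reports the error
rate (regions missing the true label) over an epsilon grid of 0.01 to
0.99 by 0.01, fine enough to resolve the curves; `efficiency_curve()`
the mean region size; `summarize_indicators()` the mean/SD of
confidence and credibility; `pca_projection()` a 2-component view with
explained-variance fractions. Curves are emitted as plain data frames
so plotting is never load-bearing.

The test suite exercises the validity property at 10 classes × 50
specimens with a 350/150 stratified holdout (error rate at each
epsilon within three binomial standard errors of the level, for all
four predictor combinations), and the aggregation-vs-induction
comparison over ten generator seeds at 10 classes × 20; the default
synthetic timing runs at 10 Hz (features depend on curve shape, not
raw rate — 100 Hz is one flag away). These sizes are the package's
choice of a desk-scale replica of the study design.

## Known limitations

* Conformal validity is marginal, not class-conditional; no Mondrian
  variant is provided.
* The bootstrap-aggregated p-value loses the exact finite-sample
  guarantee of a single ICP; its empirical calibration is checked, not
  proven.
* Forced prediction cannot discriminate among labels tied at the
  p-value floor (see above); with very small calibration sets this
  caps accuracy below 1 even for separable classes.
* The voltage-divider conversion assumes the standard readout circuit;
  instruments with other front-ends should supply resistance directly.
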