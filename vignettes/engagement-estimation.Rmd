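---
title: "Estimating dyadic engagement from peripheral physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dyadic engagement from peripheral physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When two people converse, their engagement — how interested and actively
involved they are — leaves traces in their autonomic physiology: heart rate
and its variability, electrodermal activity, respiration, and peripheral
skin temperature. Beyond each individual's arousal, engaged interaction
partners tend to *synchronize*: their physiological time courses covary.
`dyadsync` implements a complete pipeline that turns two participants' raw
multichannel recordings into per-interval engagement estimates, using both
individual and dyadic (synchrony) features, and evaluates those estimates
against self-reported engagement with crossvalidation schemes that respect
the dyadic structure of the data.

The pipeline is designed around a standard hyperscanning protocol: a 2-min
resting baseline, then 15 one-minute conversation intervals; after every
interval both participants mark their engagement on a visual analog scale
mapped to 0–100. The *reference* engagement of an interval is the mean of
the two reports. Because the reference is a mean, dyads whose members
systematically disagree are screened out before analysis (see below), and
the remaining disagreement is quantified by the one-way random-effects
intraclass correlation ICC(1,1) of the two raters.

## Pipeline overview

```{r overview}
library(dyadsync)

cohort <- gen_cohort(generator_params(n_dyads = 16, seed = 1))
result <- run_pipeline(cohort, run_config(seed = 1))
tidy(result)          # median (IQR) RMS and MA error per mode x method
autoplot(result$results$ldo_forest)
```

Stages, each exposed as ordinary functions:

1. **Ingest and segmentation** (`load_session()`, `segment()`): channels
   are validated (no NaN runs, engagement in [0, 100]), and cut into
   half-open `[start, end)` spans so adjacent intervals never share a
   sample. Self-report pauses between intervals are simply not covered by
   any span.
2. **Preprocessing** (`lowpass()`, `detect_r_waves()`, `repair_beats()`,
   `detect_breaths()`, `detect_scrs()`, `instantaneous_rate()`).
3. **Features** (`extract_features()`, `cohort_features()`): 12 individual
   features per participant per interval plus 17 synchrony features per
   interval.
4. **Estimation** (`loio_cv()`, `ldo_cv()`, `fit_regressor()`,
   `predictor_importance()`).
5. **Statistics** (`cohort_agreement()`, `icc_oneway()`, `coder_errors()`,
   `trait_error_correlations()`).

## Preprocessing choices

* **Filtering.** Skin conductance, respiration and temperature are
  lowpassed with a fourth-order Butterworth at 5 Hz. Filtering is
  zero-phase (forward–backward), because several synchrony metrics are
  lag-sensitive and a causal filter would introduce a channel-dependent
  delay. `filtfilt` on finite records leaves edge transients; we reflect-pad
  the signal (about 2–3 s) before filtering and trim afterwards, which
  keeps event detection stable near interval boundaries.
* **R-waves.** The ECG is bandpassed to the QRS band (5–30 Hz), squared,
  and peaks above an adaptive threshold are picked with a 0.25-s
  refractory period, then refined to the raw-signal extremum within
  ±40 ms. Manual beat inspection cannot be automated, so its programmatic
  analog is `repair_beats()`: any interbeat gap between 1.5× and 2.5× the
  local median interbeat interval is treated as one missed beat and an
  event is inserted *halfway* between its neighbors, flagged as
  interpolated. The flagged fraction is reported; on plausible recordings
  it should stay in the low percent range. The 1.5–2.5× gap window is our
  construction; it accepts only gaps consistent with exactly one missed
  beat.
* **SCRs.** A skin conductance response is kept when its onset-to-peak
  amplitude is at least 0.05 µS and its rise lasts less than 5 s. The
  onset is defined as the last sample before a sustained rise (first
  derivative positive for ≥ 0.2 s); only amplitude and rise-time criteria
  are inherited from the literature, so the onset rule is documented here
  and configurable. The amplitude comparison carries a 1e-12 tolerance so
  the ≥ threshold is stable under floating-point rounding.
* **Instantaneous rates.** Each interbeat (or interbreath) interval
  contributes rate 60/IBI at its midpoint; midpoints are linearly
  interpolated onto a uniform 4-Hz grid, ends held constant. 4 Hz keeps
  the 0–2 Hz respiration band below Nyquist and makes a 60-s interval a
  240-point series, which keeps the quadratic-cost synchrony metrics cheap.

## Individual features

Per participant and interval: mean heart rate, SDNN, RMSSD, pNN50 (strict
`> 50 ms`), mean skin conductance level, initial-to-final skin conductance
change, SCR count, mean SCR amplitude, mean respiration rate, SD of
respiratory periods, mean temperature, and initial-to-final temperature
change. Conventions the definitions do not fix, chosen once and used
everywhere: `mean_hr = 60 / mean(IBI)` (the rate of the mean interval, not
the mean of rates); sample (n−1) standard deviations; "initial/final"
means the first/last sample of the filtered segment; an SCR belongs to the
interval containing its *peak*.

## Synchrony features

Four metrics on four substrate pairs (instantaneous heart rate,
instantaneous respiration rate, raw skin conductance, raw skin
temperature), giving 17 values per interval:

* **DTW distance** — classic dynamic programming with absolute-difference
  local cost and the symmetric step pattern whose diagonal is weighted
  twice, accumulated cost normalized by `n + m`. Series are z-normalized
  first so amplitude differences between participants do not masquerade as
  shape dissimilarity. The inner recursion is C++ (the only compiled code
  in the package); tests pin it exactly to an independently coded
  brute-force recursion.
* **Nonlinear interdependence** — both series are delay-embedded
  (dimension 3, delay 2 samples = 0.5 s at 4 Hz) and the mean squared
  distance of each point to its k = 4 nearest neighbors is compared with
  the distance to the points at the time indices of the *other* series'
  neighbors; a Theiler window of 8 samples excludes trivially close
  neighbors. The directed measures S(X|Y) and S(Y|X) are averaged so the
  feature is symmetric under participant swap. Identical series give 1;
  independent series give small positive values. The embedding parameters
  are not fixed by the source procedure, so they are package defaults,
  exposed in `run_config()`.
* **Band-averaged magnitude-squared coherence** — Welch estimate with 30-s
  Hann windows at 50% overlap (three segments per 60-s interval),
  mean-detrended per segment; the DC bin is excluded from band averages
  since detrending empties it. Bands: respiration 0–2 Hz, heart rate
  0.1–0.15 Hz and 0.15–0.4 Hz; no published bands exist for skin
  conductance and temperature, so the defaults 0–0.5 Hz and 0–0.1 Hz
  (tonic dynamics) are package choices, configurable via `run_config()`.
  The 30-s window is the shortest giving ≤ 0.033 Hz resolution, needed to
  resolve the narrow 0.1–0.15 Hz band; with only three segments the
  estimate is biased upward, which affects both members of every
  comparison equally.
* **Cross-correlation** — the Pearson correlation at lag zero, by design
  the simplest measure and intentionally without lag search.

## Engagement estimation

Reference engagement is regressed on features with three tree-based
estimators — a CART regression tree (`rpart`, minimum leaf 3), stagewise
least-squares gradient boosting of depth-2 trees (`xgboost`, 100 rounds,
learning rate 0.1), and a random forest (`randomForest`, 100 trees) — and
compared against non-physiological median baselines. Predictions are
clipped to [0, 100] because the scale is bounded. All fits are
deterministic given a seed; a constant response short-circuits to a
constant predictor.

* **Dyad-specific** (`loio_cv()`): leave-interval-out within one dyad —
  train on 14 intervals, predict the 15th, rotate. Participant
  characteristics are excluded (constant within a dyad) and no baseline
  normalization is applied.
* **Dyad-non-specific** (`ldo_cv()`): leave-dyad-out — train on all other
  dyads, predict the held-out dyad's 15 intervals. Physiological features
  are first *baseline-normalized* (each dyad's resting-interval value
  subtracted) to reduce between-dyad offsets; age, gender code and the
  four trait scores of both participants may be appended
  (`use_chars = TRUE`). The normalization is deliberately applied only in
  this mode; the table guards itself against accidental double
  normalization.
* **Errors**: per dyad, RMS and mean-absolute error over its out-of-fold
  predictions; cohorts are summarized as median (25th–75th percentile),
  quartiles by linear interpolation (R `quantile` type 7).
* **Ablations**: `use_sync = FALSE` removes the 17 synchrony columns;
  `use_chars = FALSE` removes the 12 characteristic columns — both mirror
  the question of whether those costlier inputs buy accuracy.
* **Importance** (`predictor_importance()`): per-fold impurity importances
  normalized to sum 1, averaged over the held-out-dyad models; ranking
  ties break lexicographically by feature name. Participant roles (P1/P2)
  are kept as recorded; an augmentation with swapped roles was considered
  and left out of the default path to keep the feature semantics aligned
  with reporting conventions.

Dyad screening uses the median per-interval absolute difference between
the two raters with a default threshold of 30 points: ordinary
disagreement (about 10–15 points at calibration defaults) passes, while a
dyad whose members differ by ~40+ points on a typical interval is
excluded. No published rule exists for this screen — the original
exclusion was by inspection — so the statistic and threshold are exposed
prominently in `run_config()`.

## The synthetic cohort generator

There is no public accession for recordings of this kind, so the package
carries a first-class generator (`gen_cohort()`) whose defaults are
calibrated to the published cohort-level statistics of the protocol it
emulates: engagement pooled median 76 (IQR 64–90), between-rater absolute
difference median 13.5 (7–23), rater ICC 0.46, within-dyad engagement
range median 31 (22–39).

* **Engagement**: per dyad, a level ~ N(76, 7) plus a smooth AR(1)
  trajectory (lag-1 correlation 0.7, stationary SD 11) over the 15
  intervals, clipped to [0, 100]. Each rater reports latent + N(0, 14),
  rounded to 0.1 (VAS digitization). These values follow from closed
  forms: the difference of two rater noises is N(0, 2σ²), so
  median|Δ| = 0.954 σ ≈ 13.4 at σ = 14, and with latent variance
  V = 7² + 11² = 170, ICC ≈ V/(V + σ²) ≈ 0.46 — both at the published
  point estimates (clipping at the scale ends shrinks both slightly).
* **Coupling**: a shared band-limited (0.05–0.3 Hz) drive enters both
  participants' heart-rate and respiration-rate processes with amplitude
  `coupling × engagement/100`; a fraction of SCRs co-occurs in both
  participants with the same probability; temperature receives a heavily
  smoothed copy. `coupling = 0` is an uncoupled null cohort, 1 the
  default, 2 a strongly coupled cohort. Engagement also moves individual
  features (heart-rate level, SCR rate and amplitude), since both kinds of
  features are expected to matter.
* **Signals**: ECG is a narrow pulse train from integrate-and-fire on the
  heart-rate process — sufficient for R-wave detection, not a
  morphological PQRST; respiration is a frequency-modulated sinusoid;
  skin conductance is a slowly declining tonic level plus planted 2-s-rise
  SCRs with a minimum 8-s gap (so noise-free recovery is exact by
  construction); temperature is a slow AR(1) drift. Event ground truth is
  snapped to the sampling grid and recorded. Default sampling rate is
  100 Hz (a parameter; real recordings are often faster, but the pipeline
  consumes event times and 4-Hz substrates, which 100 Hz oversamples
  generously).
* **What it does not emulate**: real ECG/EDA morphology and artifacts,
  movement and electrode noise, conversation content, and — critically —
  the real effect size linking engagement to physiology, which is unknown
  without the original recordings. Passing recovery and ordering tests on
  this substrate therefore validates the *pipeline's mechanics*
  (detection, bookkeeping, leakage-freedom, metric correctness), not the
  field effect size.

## Numerical and testing notes

* Intervals are half-open `[start, end)`; sample *i* (1-based) lives at
  time `(i − 1)/fs`.
* Degenerate inputs: zero-variance series make Pearson correlation error
  out rather than return NaN; constant rating matrices make the ICC error
  out; constant training responses return constant predictors; constant
  trait columns yield NA correlations, reported as missing.
* The test suite exercises oracle equivalence (brute-force DTW, ANOVA
  ICC, hand HRV), analytic fixed points (identical inputs), exact
  noise-free event recovery, CV fold bookkeeping with sentinel-poisoning
  leakage checks, the qualitative orderings (learned estimators vs median
  baseline, synchrony ablation, coupling monotonicity), and generator
  calibration. Cohort-scale checks run on 16 synthetic dyads (the
  emulated cohort size) with a 4-dyad cohort for unit-level fixtures;
  surrogate-null checks use 12–20 trials with 15–19 surrogates each.
  These sizes are the package's chosen trade-off between statistical
  resolution and a test suite that stays fast enough to run routinely.
* `scripts/acceptance.R` regenerates a 16-dyad cohort from a root seed and
  recomputes every headline quantity (agreement statistics, per-method
  LOIO/LDO errors, ablations, coder comparison) from scratch.

## Known limitations

* The screening threshold, SC/temperature coherence bands, NLI embedding
  parameters and estimator hyperparameters are defensible defaults, not
  fitted quantities; sensitivity to them is untested against real data.
* Coherence from three Welch segments is upward-biased; comparisons
  across conditions are fine, absolute values should not be
  over-interpreted.
* The mean-of-two-raters reference cannot distinguish (0, 100) from
  (50, 50); screening mitigates but does not remove this.
* EDF ingest is not provided; channel data are delimited text
  (`time_s,value`), one file per participant-channel, plus a YAML
  manifest.
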