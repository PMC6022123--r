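---
title: "Detecting hemiplegic gait from trunk inertial signals without step detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hemiplegic gait from trunk inertial signals without step detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemigait)
```

## The problem and the modelling idea

Hemiplegia — one-sided motor impairment after stroke — produces a gait that
is asymmetric, slow, and unstable: the paretic side bears less load, double
support occupies more of the gait cycle, and abrupt compensation movements
punctuate the walk. A single inertial module worn at the lumbar spine
(L3–L4, near the body's centre of mass) records six channels: lateral
(`ACC_X`, +x), vertical (`ACC_Y`, +y) and longitudinal (`ACC_Z`, −z)
acceleration, plus angular velocities around the same axes (`GYRO_X`,
`GYRO_Y` = yaw around the vertical axis, `GYRO_Z` = roll around the walking
direction).

The key methodological choice is to avoid step detection entirely. Per-step
analyses inherit every step-segmentation error, and hemiplegic waveforms are
exactly the ones segmenters fail on. Instead, every attribute here is a
functional of the *whole* 20 m walk: distribution moments, interval
statistics of zero crossings and local maxima, shape moments of the power
spectrum, Poincaré plot dispersions, and autocorrelation summaries — 165
attributes in all (27 per channel plus 3 on the acceleration magnitude).
A greedy wrapper search then finds the few attributes that matter, and a
bagged decision-tree ensemble classifies.

## The attribute catalog

`feature_catalog()` declares the 165 attributes; `extract_features()`
computes them. Per channel:

* **time (15)** — mean, max, min, range, SD, variance, RMS, kurtosis
  (`TKur`), skewness (`TSkew`); number, mean interval and SD interval of
  zero crossings (`NZC`, `MZCI`, `SDZCI`); number, mean interval and SD
  interval of strict local maxima (`NLM`, `MZCIL`, `SDZCIL`).
* **spectral (7)** — dominant frequency `DF`, centroid `CF`, bandwidth `BW`,
  spectral skewness `Skew` and kurtosis `Kur`, spectral entropy `SpEnt`,
  total power `TP`. The spectrum is the rectangular-window periodogram of
  the mean-removed series with the DC bin dropped, normalised to a
  probability mass function over frequency; the moments are moments of that
  distribution. `Kur_GYROZ` — the spectral kurtosis of the roll angular
  velocity — is one of the two headline attributes.
* **Poincaré (3)** — `SD1` (dispersion perpendicular to the identity line of
  the lag-1 scatter; short-term variability), `SD2` (dispersion along it),
  and their ratio `SDR`. `SD1_GYROY`, the SD1 of yaw, is the other headline
  attribute: compensation movements and left/right asymmetry disperse
  consecutive yaw samples away from the identity line.
* **autocorrelation (2)** — the lag-1 autocorrelation `AC1` and the height
  of the first nonzero-lag autocorrelation peak `ACP`, the classic stride
  regularity index.

Conventions, stated once and tested: population (divide-by-*n*) moments
everywhere; kurtosis is non-excess (a Gaussian series scores 3); sampling
rate travels as metadata and features are deliberately not unit-normalised.
Degenerate cases (zero-variance kurtosis, single-bin spectra, fewer than two
intervals, absent autocorrelation peak) map to 0 in the final vector with a
warning, so classifiers always see finite numbers; a spectral bandwidth
below $10^{-9}$ of the frequency scale is treated as zero so that FFT
leakage (~$10^{-15}$ relative) cannot masquerade as spectral shape.

## Selection and classification

`sequential_forward_search()` starts from the empty attribute set with
criterion $+\infty$; each round evaluates every remaining attribute by the
4-fold cross-validated misclassification rate of the wrapper classifier on
the enlarged set, accepts the best (ties to the lowest catalog index), and
stops when the best improvement falls below the termination tolerance
$10^{-6}$ or the criterion would rise. The fold assignment is fixed per
search and the per-fold classifier seeds are shared across candidates, so
candidate comparisons are paired. The wrapper uses 10 trees: the training
error-versus-trees curve plateaus by about ten trees, and the wrapper is
refit thousands of times per search.

Because the selected set varies with the training sample,
`stability_rank()` repeats the search (default 100 times) on re-randomised
training sets — by default a 75% subject-level subsample without
replacement, so both walks of a subject stay together and no walk leaks
between resamples — and counts how often each attribute is chosen. The most
frequently selected attributes are the stable ones; the final classifier
uses the top two.

`train_forest()` implements bagging exactly as specified: each of up to 50
classification trees (CART, gini) is grown on a bootstrap resample of size
*n* with replacement; prediction is the majority vote with ties going to
the normal class; the out-of-bag error is the vote of only those trees not
containing a row, with rows lacking any out-of-bag tree excluded from the
denominator. `features_per_split` defaults to `sqrt` (standard
random-forest practice); `error_curves()` reports the OOB error over every
(attribute-prefix, tree-count) pair. The ensemble is implemented in C++
for two reasons: the wrapper loop needs thousands of sub-millisecond fits
per search, and the contract (vote ties, OOB definition, deterministic
split tie-breaks, seedability) is pinned without depending on another
implementation's internals — the `randomForest` package serves as an
independent cross-check in the test suite, not as the backend.

Evaluation uses the standard four measures on the held-out set, with
hemiplegic as the positive class, all in percent:
$SE = 100\,TP/(TP+FN)$, $SP = 100\,TN/(FP+TN)$,
$AC = 100\,(TP+TN)/(TP+FP+TN+FN)$, $PPV = 100\,TP/(TP+FP)$. A metric with a
zero denominator is reported as `NA`, never silently as 0 or 100, so
averaged cross-validation reports are not corrupted.

## The synthetic cohort

Clinical recordings of this kind are not publicly deposited, so the package
ships a generator (`simulate_recording()`, `simulate_cohort()`) that
emulates the statistical structure the classifier exploits rather than
trunk biomechanics. Steps alternate right/left with lognormal duration
jitter; per step the deterministic waveforms are a raised-cosine vertical
pulse (two per stride), an alternating-sign lateral half-sine, an
impulse-plus-decay longitudinal contact transient, and an alternating yaw
half-sine; `GYRO_X`/`GYRO_Z` are scaled, phase-shifted copies of yaw. The
hemiplegic mechanisms are: a paretic-side deficit $\rho$ (acceleration
amplitudes $\times(1-\rho)$, yaw $\times(1+\rho)$ on the paretic side, which
is drawn left or right per subject); amplitude flattening ($\times 0.2$)
over the final `double_support_frac` of each step; and compensation spikes —
a Poisson process of rate $\lambda$ whose events add a 100 ms biphasic
pulse to all gyroscope channels (amplitude `spike_amp` × `gyro_amp`) and to
lateral acceleration (`spike_amp` × `amp_lateral`). White Gaussian noise is
added to every channel and a 3 s quiet standby pad is prepended; a constant
+1 g gravity projection sits on `ACC_Y` until standby-mean calibration
removes it.

Two constraints keep the model physical. The gravity projection applies to
the whole recording, not only the standby pad, so calibration does not
inject a bias into the walking segment. And the lateral-acceleration and
yaw waveforms are constrained to zero mean per step: over a straight 20 m
walk the trunk returns laterally each stride and keeps its heading, so
lateral acceleration and yaw rate integrate to approximately zero; without
this constraint an asymmetric walk acquires a DC offset, and the whole-walk
*mean* of lateral acceleration becomes a perfect separator for a physically
impossible reason.

Default cohort ranges (`default_param_ranges()`) were fixed once as
clinically plausible: hemiplegic subjects walk slower (step period
1.2–1.5 s vs 1.0–1.25 s, with overlap, since mildly affected patients and
slow normal walkers overlap in cadence), take more, shorter steps over the
same distance, show longer double support (30–45% vs 15–25%), higher
cadence variability, a paretic deficit $\rho \in [0.3, 0.5]$ and spikes at
$\lambda \in [0.3, 0.7]$ Hz. Cohorts draw one profile per subject and two
walks per subject with per-walk sub-seeds, so any element is reproducible
in isolation.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: inter-subject waveform morphology, gait
initiation/termination transients, turning, soft-tissue artefact, sensor
misplacement, bilateral hemiplegia, and severity heterogeneity beyond the
uniform parameter ranges. The synthetic task is easier than the clinical
one: at strong effect sizes ($\rho = 0.4$, $\lambda = 0.5$ Hz) many single
attributes already separate the classes with zero cross-validated error,
where the clinical data needed two attributes. One consequence is worth
stating plainly: when many attributes tie at zero error, the deterministic
tie-break (lowest catalog index) hands every stability count to the
earliest such attribute — a lateral-acceleration time-domain attribute,
since the spike model also marks `ACC_X` and that channel comes first in
the catalog — so the stability ranking on easy synthetic cohorts surfaces
`Max_ACCX`-type attributes rather than the gyroscope Poincaré/spectral
attributes that dominate on harder, real data. The held-out accuracy is
unaffected.

## Numerical and design choices

* **Sampling rate** defaults to 100 Hz in the simulator and is inferred
  from the time column (median inter-sample interval, snapped to an integer
  when within $10^{-6}$ relative) for files, with a >1% mismatch against a
  declared rate treated as an error.
* **Standby detection** is a 1 s moving-window SD of the acceleration
  magnitude against a threshold (default 0.05 g); the walking segment is
  the contiguous span between the first and last active windows.
  Calibration subtracts per-channel standby means (gravity projection and
  gyro bias).
* **Splits**: stratified 75/25, grouped by subject so both walks stay on one
  side; with 15 + 20 subjects this yields 52 training and 18 test walks
  (10 hemiplegic, 8 normal). K-fold partitions are random equal-size (±1)
  folds, redrawn (up to 100 times) until every training fold holds both
  classes.
* **Tie-breaks** are deterministic everywhere: candidate ties to the lowest
  catalog index, vote ties to the normal class, split ties to the lowest
  feature index then lowest threshold.
* **Determinism**: every stochastic function takes a seed and derives
  sub-seeds through one documented helper; reruns of `run_pipeline()` with
  the same config are bit-identical.
* **Problem sizes** used in the shipped checks: the study-scale cohort
  (15 + 20 subjects × 2 walks), 100 stability iterations, 50-tree final
  ensembles, and 20 master seeds for the end-to-end average — sizes chosen
  to mirror the study design while keeping a full run in minutes on one
  CPU.

## A short run

```{r example, eval = FALSE}
cfg <- run_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "hemigait_run")
res$selected        # the two attributes the final classifier uses
res$metrics         # held-out SE / SP / AC / PPV
```

## Limitations

The synthetic cohort validates the machinery, not clinical performance;
accuracy on these cohorts says nothing quantitative about accuracy on
patients. The forward search is greedy and the stability ranking inherits
its biases (notably the catalog-order tie-break under ties). The classifier
is deliberately small (≤50 trees) and uncalibrated; no probability outputs,
ROC analysis, or confidence intervals are provided.
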