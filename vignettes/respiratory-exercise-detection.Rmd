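---
title: "Detecting exercise in nasal-pressure breathing signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting exercise in nasal-pressure breathing signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`respirex` asks a concrete telemonitoring question: given 45-second windows
of the nasal-pressure signal recorded in an oxygen-therapy circuit, which
window-level summaries of the breathing pattern best distinguish resting
breathing from breathing under physical effort — and do they still work when
the detector may learn only from a patient's *normal* breathing? This
vignette is the package's own account of the models it implements, the
parameters that matter, and the design decisions taken where the design was
genuinely open.

## The signal and its simulation

Inspiration through a nasal cannula produces a pressure *minimum*, so the
respiratory waveform proxy is a train of downward troughs. The synthetic
generator builds each breath cycle from three phases: a half-sine
inspiratory trough below baseline (35% of the cycle), a shallower expiratory
recovery hump (25%, height 15% of the inspiratory depth), and an
end-expiratory pause at baseline (40%). The pause is deliberate: it is
physiologically ordinary, and it anchors the rolling-median baseline
estimate at the true zero line, which keeps depth measurement unbiased.

Cycle lengths and inspiratory depths are drawn from gamma distributions
(positive support, so no degenerate negative cycles) around the regime's
means, with subject-level coefficients of variation. Defaults were chosen
once as typical resting physiology: 15 breaths/min, amplitude 1 (arbitrary
pressure units), breath-length CV 0.12, depth CV 0.15, white sensor noise
SD 0.12, and a slow sinusoidal baseline drift of amplitude 0.1 with a
60-second period. Cycle lengths are truncated below at 0.5 s: 2 Hz is the
ceiling above which a breathing rate has no physiological sense, and the
generator guarantees the true instantaneous rate never crosses it.

Subjects differ in how they meet an increased respiratory load. The
`strategy` field encodes this: a *rate-dominant* subject multiplies rate by
1.7 and amplitude by 1.35 during exercise (breathing faster also deepens
breathing somewhat), an *amplitude-dominant* subject keeps their rate and
doubles their depth, and *mixed* subjects sit in between (1.4 / 1.6).
Cohorts alternate strategies, which is precisely what makes breathing rate
alone a weak pooled discriminator: for half the cohort it carries almost no
signal.

Two protocols are generated. The **healthy protocol** is a scripted
30-minute recording — 23 windows of reference breathing containing four
artifact events (drinking, coughing, speaking, mouth breathing) at fixed
times, 4 windows (3 min) of exercise, and 13 windows of recovery in which
rate and amplitude decay exponentially back to rest (time constant 120 s,
so early transition windows are genuinely intermediate). Because the three
phases are exact multiples of 45 s, windowing yields the 23/4/13 label
structure for every seed. Artifacts remain labelled *reference*: they are
everyday normality, and a useful novelty detector must tolerate them. The
**observational protocol** emulates a long ward recording: reference
breathing with absence gaps (cannula off; pure sensor noise), a
configurable number of exercise blocks at randomized positions, and
optional label noise that blurs exercise-block edges by up to two windows
in the *reported* schedule while the truth is retained — mimicking exercise
sessions whose clock times are only approximately known. Label noise is
boundary blur, not random flips, because scheduling error is the actual
mechanism.

The generator emits a ground-truth side channel (`$cycles`: every true
trough time, cycle length and depth), so breath detection is scored against
truth rather than against itself. What the simulation does **not** emulate:
real sensor physics, oxygen-flow dynamics, posture/movement artifacts
beyond the four scripted types, apnea, periodic breathing, or the
slow circadian drifts of real ward data. Tests passing on this generator
therefore demonstrate the *machinery* — segmentation fidelity, absence of
leakage, estimator calibration, metric correctness, and the direction of
the feature-set comparison under strategy heterogeneity — not clinical
performance on real recordings.

## Preprocessing

Windows are exactly 45 s (450 samples); a trailing partial segment is
discarded, never padded, so the Fourier period T stays fixed. Window labels
come from the majority regime, ties broken toward the earlier regime;
artifact spans count as reference; absent-majority windows are excluded.

**Presence.** A subject is present when mean spectral power in the
respiratory band (0.1–2 Hz) is at least `presence_threshold` (default 3)
times the broadband noise floor estimated above 2.5 Hz. White sensor noise
has a flat spectrum (ratio near 1); any real breathing concentrates power
below 2 Hz. The boundary case counts as present. Attenuating artifacts
(drinking, mouth breathing) can genuinely fail this test — those windows
are excluded rather than mis-measured.

**Breath segmentation.** Troughs are prominence-filtered local minima of a
lightly smoothed signal (moving average, `smooth_s = 0.3` s) with a minimum
separation of 0.5 s (the 2 Hz ceiling again). The prominence threshold
defaults to 25% of the window's robust range (5th–95th percentile), making
it scale-free across subjects. Two refinements follow: the *depth* of each
breath is the raw signal's deepest sample within ±0.2 s of the detected
trough, measured against a rolling-median baseline (5 s window) — robust to
drift, cheap, reproducible; the *time* of each trough is the centroid of
the smoothed dip within ±0.5 s, which averages out the noise that displaces
a bare argmin by several samples and gives sub-sample timing. On the
default generator this detector matches over 95% of true troughs within
±0.2 s (the acceptance script reports the figure it achieves at run time).

**Quality.** Windows with fewer than 4 identified breaths are
`too_few_breaths` — a hard rule that overrides every other setting — and
windows whose cycle-length CV exceeds `max_cycle_cv` (default 0.5, a value
left open by the problem statement and exposed in the configuration) are
`too_variable`. Only `ok` windows contribute features.

## Features

* **Breathing rate** = 1 / median(cycle length), in Hz. Median, not mean:
  one swallowed or missed breath should not move the estimate.
* **Amplitude** = median inspiratory depth (baseline − minimum).
* **ARIMA(1,1,1)**: exact maximum likelihood on the differenced series
  (an ARMA(1,1) with constant), via `stats::arima`. The model's prediction
  equation *subtracts* the moving-average term, while R's convention adds
  it, so the reported θ is `-ma1`; the drift μ is `intercept × (1 − Φ)`
  because R parameterizes the mean of the differenced series. A unit test
  guards the sign mapping by simulating the prediction equation literally.
  Stationarity and invertibility are enforced by the estimator's parameter
  transformation; constant windows and non-converging fits yield flagged
  missing values. One caveat documented by a test: on a pure random walk
  the AR and MA roots cancel and Φ, θ are individually weakly identified —
  only μ and Φ − θ are stable there.
* **Fourier magnitudes**: |c_n| with c_n = (1/T)∫f(t)e^{−inωt}dt,
  evaluated as FFT/N, which *is* the rectangle-rule discretization of that
  integral on the sample grid; an FFT-vs-direct-integration oracle pins
  this equivalence to 1e−8. Bins up to 2 Hz inclusive are kept (n = 0…90 at
  T = 45 s, resolution 1/45 Hz ≈ 22 mHz). The DC bin is retained by default
  (it encodes baseline level, not breathing, so a switch removes it); the
  2 Hz boundary bin is included. No detrending or tapering is applied
  before the FFT. Magnitudes only — phases are discarded.

For both classifiers the 91 Fourier magnitudes are reduced to 5 principal
components. The PCA is always fitted on training rows only and refitted
inside every cross-validation fold; a leakage test verifies that perturbing
held-out rows cannot change loadings or downstream models.

## Classification

**Supervised.** A binomial GLMM with logit link: exercise vs reference,
per-subject random intercepts and random slopes on every covariate of the
feature set, with a *diagonal* random-effect covariance — the most literal
identifiable reading of "random intercepts and random slopes" at these
sample sizes. Covariates are standardized internally. Clean synthetic
cohorts can separate the classes perfectly, which breaks `lme4::glmer`'s
PIRLS iterations outright, so fitting walks a ladder: glmer (Laplace) →
glmer (nAGQ = 0) → `glmmTMB` with the same diagonal-slope structure →
random-intercept-only (glmer, then glmmTMB) → plain fixed-effects logistic
regression. The rung used is recorded in the fitted object (`$spec`).
Because no evaluation protocol is canonical here, both are implemented:
5-fold cross-validation with folds stratified within subject and class
(every subject appears in every training fold, keeping its random effects
estimable; the default) and in-sample evaluation. This protocol choice is
the largest open gap in the supervised comparison and is surfaced as an
explicit option rather than hidden.

**One-class.** Per subject, reference windows only: mean μ and covariance
Σ, scored by the Mahalanobis distance computed via Cholesky triangular
solves (no explicit inverse; an oracle test pins it to the explicit-inverse
form at 1e−10). Small training folds with up to 5 features can make the
sample covariance singular, so Σ is shrunk toward its diagonal with a
data-driven (Ledoit–Wolf-style) intensity, logged in the model object;
`lambda = 0` recovers the raw covariance. Folds are contiguous blocks of
reference windows by default — random assignment is available, but
contiguous blocks are honest under temporal autocorrelation. The healthy
scheme scores all exercise windows in every fold (five predictions each,
matching the scarcity of exercise windows there); the observational scheme
partitions exercise windows across folds too (one prediction per window).
Subjects need at least 10 usable reference windows or they are skipped with
a logged warning.

## Evaluation

Scores are pooled across subjects (per-subject aggregation is available);
the empirical ROC groups tied scores into single steps, so the trapezoidal
AUC equals the tie-corrected Mann–Whitney statistic exactly — a property
tested, not assumed. The 95% CI uses DeLong's method by default (stratified
bootstrap optional). The operating point minimizes the distance to the
upper-left ROC corner, √(FPR² + (1 − TPR)²), ties broken toward higher
sensitivity. The distance formula is sometimes printed with (1 + TPR)²; that
variant is minimized at TPR = 0 and contradicts the upper-left-corner
intent, so the package treats it as a typographical slip, defaults to the
corrected form, and keeps the literal one behind
`cutoff_formula = "as-printed"` for audit. Accuracy, sensitivity and
specificity are recomputed from the raw scores at the selected cut-off
(call exercise when score ≥ cutoff), so the reported panel is internally
consistent by construction.

## Problem sizes and runtime

The test-suite and acceptance-script cohorts are sized for a single CPU:
12 healthy subjects (30-minute protocol) and 4 observational subjects at
2 h for the feature-set comparison; 200 replicates for the ARIMA recovery
and DeLong coverage simulations; 50 seeded windows for segmentation
fidelity. These sizes give stable directional results (the rate-only AUC
gap to every other feature set is large) while keeping a full run in
minutes. Larger cohorts are a configuration change
(`experiment_config(n_healthy = 20, n_copd = 8, copd_hours = 8)`), not a
code change.

## Known limitations

* The generator's artifacts are stylized bursts; real swallowing, speech
  and movement are richer, so real-data reference classes are noisier than
  simulated ones.
* ARIMA features react to amplitude partly through the signal-to-noise
  ratio (sensor noise is additive and fixed), an interaction a different
  noise model would change.
* The supervised and one-class frameworks share windows but not an
  evaluation protocol; cross-framework AUC comparisons inherit the
  protocol choices above.
* Transition windows are labelled but never used for classification —
  deliberately, as they are neither rest nor effort.
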