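---
title: "Models and methods behind the fiberspec readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the fiberspec readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fiberspec is a digital twin of a multiplexed fiber-optic fluorescence
monitor for six cerebrospinal-fluid biomarkers, plus the complete inverse
pipeline that turns spectra back into concentrations. This vignette
explains the models, the tunable parameters and their defaults, the
numerical choices, and what the simulator does and does not emulate.

## 1. The forward model

### Response curves

Each sensing film's emission is summarized by a dimensionless ratio
R = I/I₀ relative to its reference condition, where R is exactly 1.
Three curve families cover the six chemistries:

| channel | family | parameters | reference | valid range |
|---|---|---|---|---|
| temperature | Stern–Volmer | I₀/I = 1 + 0.04 (T − 33) | 33 °C | 33–42 °C |
| dissolved O₂ | Stern–Volmer | I₀/I = 1 + 0.38 [DO] | 0 mg/L | 0–8 mg/L |
| pH | logistic4 | midpoint 7.0, k ≈ 2.0 | pH 6 | 6–8 |
| Na⁺ | linear ratio | I/I₀ = 1 + 0.0064 [Na⁺] | 0 mmol/L | 0–200 mmol/L |
| Ca²⁺ | logistic4 | midpoint 0.5 (K_d), k = 2 | 0 mmol/L | 0–3 mmol/L |
| glucose | logistic4 | midpoint 3.0, k = 1 | 0 mmol/L | 0–6 mmol/L |

The logistic4 form is R(c) = A + (B − A)/(1 + e^{−k(c − c₀)}). Its free
amplitudes are not quoted directly by the characterization facts, so they
are *solved* from them, once, in closed form:

* **pH** — three constraints: R(6) = 1, R(8)/R(6) = 5, and midpoint slope
  (B − A)k/4 = 2.624 per pH unit. Eliminating the amplitudes leaves
  (4·2.624/k)·tanh(k/2) = 4, solved by `uniroot` to k ≈ 1.9965.
* **glucose** — k = 1 and c₀ = 3 (center of the working range) are fixed;
  the amplitudes are solved from R(0) = 1 and R(5)/R(1) = 4.
* **Ca²⁺** — c₀ = 0.5 mmol/L (the indicator's dissociation constant) and
  k = 2 per mmol/L are fixed; k = 2 leaves the curve ~95% saturated at
  2 mmol/L, so the excitotoxic scenario value of 3 mmol/L is
  representable. The amplitude is solved so that the ordinary
  least-squares slope of R over the physiological window grid
  (1.0, 1.1, 1.2, 1.3 mmol/L — the 0.1-step sweep points inside the
  1.0–1.35 window) equals 0.41 per mmol/L. Defining the constraint on
  the discrete sweep grid rather than the continuous interval makes the
  calibration convention explicit and reproducible.

The quenched channels (temperature, DO) are *evaluated* as
I/I₀ = 1/(1 + slope·x): `evaluate_response()` always returns the factor
the peak amplitude is multiplied by. Curve inversion
(`invert_response()`) is closed-form for all three families (logit for
the logistics), which the classical non-ML readout path and the
two-point calibration rely on.

Two printed figures are deliberately *not* enforced: the DO "reduced by
85.6%" statement is incompatible with a unit-intercept Stern–Volmer line
of slope 0.38, and the abstract's Ca²⁺ sensitivity of 0.33 conflicts
with the characterization section's 0.41; the characterization values
win in both cases.

### Spectra

One laser's frame is 460 pixels; the merged measurement vector is the
concatenation [405 | 488 | 520] of length 1380, with peaks at merged
indices 34 (pH), 28 (glucose), 341 (DO), 725 (Na⁺), 884 (temperature),
1262 (Ca²⁺), 0-based. Peaks are Lorentzian (default FWHM 30 px, base
amplitude 1000 arbitrary units) and superpose additively. Note the
glucose peak index (28) sits *below* the pH index (34); the index
semantics are instrument pixel order, not emission-wavelength order.

A channel's amplitude is

    base_amplitude × R(state) × exp(−exposure/τ) × exp(−q·(T − 33))

The last factor is temperature cross-quenching: every fluorophore dims
as temperature rises. Its magnitude is not quoted anywhere, so q
defaults to a mild 0.005/°C for the five non-temperature channels and to
0 for the temperature channel itself, whose response curve *is* its
temperature dependence (a second factor would double-count). Set
`cross_temperature_coeff = 0` to disable it.

The baseline model is `amplitude·exp(−decay·px) + quadratic` (defaults
150, 0.002/px, 20 + 0.02·px − 1e-4·px²), a gentle long-range drift of
the kind baseline correction is meant to remove, plus i.i.d. Gaussian
noise (default σ = 2, i.e. 0.2% of base amplitude). Setting every
`noise_config()` field to 0 gives a noiseless, baseline-free spectrum —
the oracle mode most tests use.

### Photobleaching and exposure units

Bleaching follows I(t) = I₀e^{−t/τ} with per-film constants
τ = {51.13, 48.8, 37.0, 22.0, 38.0, 133.7} for
{T, DO, pH, Na⁺, Ca²⁺, glucose}. The τ values were fitted to
*continuous*-exposure photostability data, but the instrument runs
*pulsed* (5 s on / 5 s off), which empirically slows bleaching by orders
of magnitude. The package therefore keeps two clocks: frames and
exposure ledgers count laser **on-time in seconds** (720 cycles = 3600 s
per laser), while bleaching uses **abstract exposure units** =
on-seconds × `exposure_units_per_s` (default 0.01 in
`pulse_schedule()`). Calibration sweeps bypass the schedule and assign
exposure units directly (`max_exposure = 20` across a sweep, leaving the
fastest-bleaching film, Na⁺ with τ = 22, at ~40% retention).

## 2. The inverse pipeline

The order is fixed and recorded in each spectrum's provenance:
denoise → baseline-correct → (standardize) → merge → label →
extract → photobleach-correct → select → regress.

### Smoothing

Savitzky–Golay, window 11, order 3 (no values are quoted for the
instrument; these are the field's workhorse settings for peaks tens of
pixels wide). Polynomials up to the chosen order pass through unchanged.

### Baseline correction

`baseline_correct()` is penalized least squares: minimize
Σ wᵢ(yᵢ − zᵢ)² + λ Σ (Δ²z)² over baselines z. The default method is an
adaptive-reweighting scheme: an airPLS-style pass (points above the
current baseline are progressively down-weighted to zero, with an early
exit when almost nothing lies below) followed by three re-fits of a
stiff baseline (100λ) restricted to the classified baseline support
(points within max(0.006·max(d), 3·rms(negative residuals)) of the
current baseline). The classic fixed-asymmetry scheme (weight p above,
1 − p below; p = 0.01) is available as `method = "als"`.

The two-stage default exists because Lorentzian tails are heavy: on a
460-pixel segment a FWHM-30 peak contributes several percent of its
height *everywhere*, and a fixed-asymmetry baseline rides up on those
tails, shaving ~20% off peak heights. The support-refit keeps the
baseline anchored only where no peak evidence exists. Measured behavior
(all deterministic, asserted in the tests): residual < 1% of amplitude
on a peak-free slowly-decaying exponential; mid-segment peak height
recovered within 2% on the default drift; re-application changes the
result by < 0.5% RMS for mid-segment frames. Both methods are exactly
scale-equivariant, so peak-height *ratios* — the quantities all
sensitivities are computed from — are unaffected by the residual shave.

Known limitation: the 405 segment's left margin. The pH/glucose peaks
sit 28–34 px from the segment edge, so their tails and any baseline are
mathematically confounded there; no baseline estimator can separate
them, and idempotence degrades to ~2% in that segment. The regression
layer absorbs the (systematic, deterministic) residual.

### Features

Per channel, five features:

* **height** — intensity at the channel's *fixed* nominal index. The six
  peaks are read at fixed instrument wavelengths; this is also what
  keeps the overlapped pH/glucose pair linearly separable (the two fixed
  indices give two independent mixtures of the two amplitudes).
* **position** — located local maximum within ±15 px of the nominal
  index (peaks shift slightly with concentration); nominal index if no
  local maximum exists.
* **prominence** — located peak height above the higher flanking local
  minimum; **width** — full width at half prominence (linear
  interpolation at the crossings); **area** — trapezoidal integral
  between the flanking local minima.

The flanking-minima boundary rule is noise-structure dependent: with
noise the nearest local minima sit a few pixels from the peak, in
noiseless spectra at the segment edges. Consequently area and width are
only comparable *within* one noise regime, and a regression bundle must
be applied to data of the regime it was trained on. This is asserted
and discussed in the monitor tests.

Photobleaching compensation multiplies the intensity-like features
(height, area, prominence) by e^{t/τ} with the channel's exposure;
width and position are untouched (a bleaching Lorentzian keeps its
shape). Prominence is corrected like height — it is the same physical
quantity — although no statement fixes this. Correction happens
*before* selection and training, and the corrected state is carried as
an attribute: re-correcting, or predicting from uncorrected features,
is an error. For overlapped peaks the correction is exact only for each
film's own contribution; a neighbour's tail bleaches with its own τ, a
second-order residual the regression layer handles.

`fit_tau()` recovers τ from a decay trace by log-linear least squares
refined with Levenberg–Marquardt on the original scale; noiseless traces
reproduce τ to < 1e-6 relative.

Feature selection computes Pearson r between every feature and every
label; a feature survives if max |r| ≥ 0.5 (no cutoff is quoted; 0.5 is
the conventional "strong correlation" line). Zero-variance features get
r = 0 with a warning. On the default simulation the intensity features
(heights, areas) are always selected; positions of isolated channels
never are.

### Calibration

`calibrate_channels()` re-fits every response curve from simulated
single-film characterization sweeps through the full pipeline (OLS for
the linear families, Levenberg–Marquardt via minpack.lm for the
logistics), storing per-channel reference intensities.
`two_point_calibrate()` is the session correction against two standard
buffers (defaults: (34 °C, 2 mg/L, pH 6.5, 40, 0.4, 1) and (40 °C,
7 mg/L, pH 7.8, 160, 1.6, 5) — low/high anchors differing in every
analyte, standing in for the unavailable published buffer table): per
channel it solves the affine map h = offset + gain·ref·R(c) through the
two measured points, so inversion at the standards is exact by
construction. The correction acts on *features* (the earliest point
where channel identity exists), not on raw spectra or predictions. A
pure laser-power drift is absorbed entirely by the gain (gain = drift
factor, offset ≈ 0); cross-talk between overlapped channels lands in
the offset.

### Regression

Four families, each fit per biomarker on the shared selected-feature
vector ("multitask by shared features" — six labels, no parameter
sharing): ordinary least squares; ridge and lasso via glmnet with the
penalty chosen from a 7-point log grid 1e-4…1e2 by 10-fold
cross-validated MSE; and Bayesian linear regression with conjugate
Gaussian priors whose two precision hyperparameters are maximized under
the evidence approximation (the standard iterative γ-update on the
eigendecomposition of XᵀX). Features are internally centered and scaled
for conditioning; stored coefficients are on the original scale, so
bundles serialize to plain JSON. The protocol is a deterministic 75/25
split followed by 10-fold CV on the training part (seeds recorded in
the bundle); refitting with the same seed reproduces identical
parameters.

### Monitor

`run_monitor()` replays the measurement loop: per scan the fixed
pipeline runs and the six predictions enter 100-entry circular buffers;
the display value is the mean of the 34 most recent entries. The quoted
timing is internally inconsistent — 34 points in 5 minutes implies
~8.8 s/scan, while 3 lasers × (5 s + 5 s) implies 30 s/scan; the
34-point window is kept as stated and the scan period is configurable,
defaulting to 30 s. Scenario stages (healthy, hypoxia 38 °C/3.2 mg/L,
hypermetabolism 39 °C/3.8 mg/L/1 mmol/L glucose, excitotoxicity pH
6.5/180 mmol/L Na⁺/3 mmol/L Ca²⁺) ramp linearly over a configurable
transition time, then hold. `track_scenario()` scores readout against
truth per stage (MSE/MAE) and reports detection latency — time until
the *averaged* readout crosses halfway to the new target — which is
necessarily a multiple of the scan period and, with a 34-point window
at 30 s/scan, of order 10 minutes; the instantaneous readout reacts
within one scan.

## 3. What the simulator does and does not emulate

Emulated: per-channel calibration responses with the printed
sensitivities; severe pH/glucose spectral overlap; exponential
photobleaching with per-film constants and exposure accumulation across
a sweep; temperature cross-quenching; baseline drift and additive
detector noise; pulsed three-laser scheduling; session-to-session gain
drift (via `base_amplitude`).

Not emulated: triplet-state photophysics or oxygen-diffusion kinetics;
wavelength-axis calibration (everything is pixel-indexed); fiber-optic
coupling and attenuation; non-Gaussian or correlated detector noise;
reagent aging beyond the single-exponential bleach; matrix effects of
real CSF (proteins, scatterers); hardware timing. Passing tests
therefore demonstrate that the *algorithms* invert the stated forward
model at realistic noise levels — not that the physical instrument
achieves these numbers on patient samples.

## 4. Numerical choices and degenerate inputs

* Logistic fitting: Levenberg–Marquardt (minpack.lm), initialized from
  the data range and a midpoint hint, 500 iterations; non-convergence is
  an error carrying the start values. Decreasing data yield k < 0.
* `fit_tau` refuses nonpositive intensities, < 3 points, constant series
  and non-decaying series.
* Curve inversion clips to the attainable ratio range only in
  `predict_classical()` (flagged use); bare `invert_ratio()` raises an
  out-of-range error naming the nearest bound.
* Whittaker systems are solved with sparse Cholesky (Matrix); the
  second-difference penalty matrix is cached per segment length.
* Peak search tie-break: among local maxima in the window the highest
  wins; plateaus count as maxima at their left edge pixel.
* Zero spectra pass through baseline correction unchanged; peakless
  spectra skip the support-refit (the provisional fit is already the
  baseline).
* All stochastic steps (grid subsampling, fold assignment, noise) are
  seeded; identical seeds give bit-identical datasets, splits and fits.

## 5. Problem sizes

The test suite trains on subsampled factorials of 400–1000 scans and the
acceptance script on ~2000 scans (5 levels per biomarker, subsampled);
characterization sweeps use 9–21 points per channel. These sizes hold
the full-protocol accuracy checks to a few CPU-minutes while keeping
every biomarker's held-out R² estimate stable to the second decimal.
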