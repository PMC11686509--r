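# fiberspec

Simulation and chemometric readout for a multiplexed fiber-optic
fluorescence sensing system that monitors six cerebrospinal-fluid (CSF)
biomarkers — temperature, dissolved oxygen (DO), pH, Na⁺, Ca²⁺ and glucose
— through one optical fiber bundle. The package is aimed at instrument and
algorithm developers who need a faithful digital twin of such a system:
every stage of the signal chain, from photon emission to displayed
concentration, is available as a testable R function.

## The measurement problem

Three lasers (405, 488, 520 nm) fire in pulsed cycles (5 s on / 5 s off)
and excite six fluorescent sensing films. Each laser yields a 460-pixel
emission spectrum; the three spectra are concatenated into a 1380-point
measurement vector in which the six sensor peaks sit at fixed indices
(pH 34, glucose 28, DO 341, Na⁺ 725, temperature 884, Ca²⁺ 1262). Two
physical complications make naive curve reading fail:

* **Spectral overlap.** The pH/glucose peaks (and to a lesser degree
  Na⁺/temperature) overlap severely, so one analyte's peak height depends
  on its neighbours.
* **Photobleaching.** Each film's emission decays as
  I(t) = I₀·exp(−t/τ) with accumulated excitation, with per-film
  constants τ = 51.13 (T), 48.8 (DO), 37.0 (pH), 22.0 (Na⁺), 38.0 (Ca²⁺)
  and 133.7 (glucose) in exposure-time units.

The per-channel calibration responses are the field's standard forms:
linear intensity-ratio curves I₀/I = 1 + 0.04·(T − 33) for temperature and
I₀/I = 1 + 0.38·[DO] for oxygen (Stern–Volmer quenching), a linear
I/I₀ = 1 + 0.0064·[Na⁺] for sodium, and four-parameter logistics
R(c) = A + (B − A)/(1 + e^{−k(c − c₀)}) for pH (midpoint 7.0, midpoint
slope 2.624 per pH unit, 5-fold increase from pH 6 to 8), glucose (4-fold
increase from 1 to 5 mmol/L) and Ca²⁺ (midpoint at the indicator K_d of
0.5 mmol/L, window slope 0.41 per mmol/L).

The inverse pipeline mirrors the instrument software: Savitzky–Golay
smoothing → penalized least-squares baseline correction → per-laser
standardization → merging → peak feature extraction (height, width, area,
position, prominence) → photobleaching compensation
(height ← height·e^{t/τ}) → Pearson-correlation feature selection →
multitask regression (linear, ridge, lasso, or evidence-maximized Bayesian
linear regression; 75/25 train/test split with 10-fold cross-validated
tuning) → streaming readout with six 100-entry circular buffers and a
34-point display average.

## Worked example

```r
library(fiberspec)

## 1. Characterize the dissolved-oxygen channel through the full spectral
##    round trip (simulate -> denoise -> baseline-correct -> extract):
cur <- measure_response_curve("dissolved_oxygen", 0:8)
fit_linear_ratio(cur$value, cur$quench_ratio)$slope
#> [1] 0.38

## 2. Train the multitask readout on a simulated factorial calibration run:
scans <- generate_calibration_set(n = 1000, seed = 42)   # ~1 min
tab   <- build_feature_table(scans)                      # preprocess + extract + correct
sel   <- pearson_select(tab[, feature_cols(tab)], tab[, label_cols(tab)], 0.5)
split <- split_train_test(tab, 0.75, seed = 42)
fit   <- tune_and_train(split$train, "bayesian", folds = 10, seed = 42,
                        selection = sel)
fit   <- evaluate_bundle(fit, split$test)
fit$test_scores
#>          biomarker         mse        mae        r2
#> 1      temperature 0.019088833 0.12153665 0.9954100
#> 2 dissolved_oxygen 0.126008191 0.31204277 0.9618738
#> 3               pH 0.001034776 0.02721935 0.9950141
#> 4           sodium 0.302955168 0.44592972 0.9998301
#> 5          calcium 0.003881665 0.05746414 0.9783987
#> 6          glucose 0.014173622 0.10518493 0.9931501
```

Each row is one biomarker's held-out accuracy: mean squared error and mean
absolute error in the biomarker's own units (°C, mg/L, pH units, mmol/L),
and R², the fraction of concentration variance the readout explains. All
six R² values clear 0.93 even though pH and glucose share one overlapping
peak region and every feature was distorted by photobleaching before
correction — the two effects the regression layer exists to absorb.

```r
## 3. Stream a monitoring scenario (hypoxia episode) through the readout:
scn <- generate_scenario(c("healthy", "hypoxia"), noise = noiseless_config())
mon <- run_monitor(scn, fit)
tail(mon$series[, c("timestamp", "stage", "temperature_avg",
                    "dissolved_oxygen_avg")], 1)
#>    timestamp   stage temperature_avg dissolved_oxygen_avg
#> 41      1200 hypoxia        37.76495             2.052817
```

The temperature readout tracks the 38 °C hypoxia target; the DO readout
undershoots the 3.2 mg/L target because this bundle was trained on noisy
spectra and then applied to a noiseless stream — the peak-area feature's
integration boundaries (flanking local minima) depend on the noise
structure, so a bundle must be applied to data of the regime it was
trained on. The monitor tests use a noiseless-trained bundle, which
tracks both targets to within 0.2 mg/L; the methods vignette discusses
this limitation.

A command-line driver wrapping the same functions is installed at
`inst/cli/fiberspec` (subcommands: simulate, features, calibrate, train,
evaluate, predict, monitor).

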