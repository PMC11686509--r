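Package: fiberspec
Title: Simulation and Chemometric Readout for Multiplexed Fiber-Optic
    Fluorescence Biosensing of Cerebrospinal-Fluid Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and inverse readout for a three-laser,
    six-channel fiber-optic fluorescence sensing system measuring
    temperature, dissolved oxygen, pH, sodium, calcium and glucose in
    cerebrospinal fluid. Provides a physically structured spectral
    simulator (per-channel calibration response curves, Lorentzian
    emission peaks, exponential photobleaching, baseline drift and
    noise under a pulsed excitation schedule), the full chemometric
    pipeline (Savitzky-Golay smoothing, penalized least-squares
    baseline correction, standardization, spectral merging, peak
    feature extraction, photobleaching compensation, Pearson feature
    selection), per-channel calibration-curve fitting with a two-point
    session correction, multitask regression (linear, ridge, lasso and
    Bayesian families with cross-validated tuning), and a streaming
    monitor with circular readout buffers, scenario tracking and
    spike-recovery evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    signal,
    minpack.lm,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
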