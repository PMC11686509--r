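# Shared simulation fixtures, built lazily once per test run. The heavier
# objects (preprocessed feature tables, trained bundles) are cached so the
# regression, monitor and acceptance files can share them.

.fx <- new.env(parent = emptyenv())

fx_get <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# default-noise factorial calibration table, the "default simulated
# calibration set" (subsampled factorial, exposures 0..20, seed 42)
fx_noisy_tab <- function() {
  fx_get("noisy_tab", function() {
    scans <- generate_calibration_set(n = 1000, seed = 42)
    suppressWarnings(build_feature_table(scans))
  })
}

fx_noisy_selection <- function() {
  fx_get("noisy_sel", function() {
    tab <- fx_noisy_tab()
    suppressWarnings(pearson_select(tab[, feature_cols(tab)],
                                    tab[, label_cols(tab)], 0.5))
  })
}

# noiseless oracle bundle for end-to-end monitor checks
fx_oracle_bundle <- function() {
  fx_get("oracle_bundle", function() {
    scans <- generate_calibration_set(n = 400, noise = noiseless_config(),
                                      seed = 7)
    tab <- build_feature_table(scans)
    sel <- suppressWarnings(pearson_select(tab[, feature_cols(tab)],
                                           tab[, label_cols(tab)], 0.5))
    split <- split_train_test(tab, seed = 42)
    tune_and_train(split$train, "bayesian", folds = 10, seed = 42,
                   selection = sel)
  })
}

# single-channel frames (characterization mode): one film's emission with
# the other lasers' segments dark
single_channel_merged <- function(channel, state, exposure = 0,
                                  noise = noiseless_config()) {
  fr <- emit_spectrum(channel, state, exposure = exposure, noise = noise)
  frames <- lapply(c(405, 488, 520), function(l)
    if (l == channel$excitation_nm) fr else
      spectral_frame(l, numeric(segment_length())))
  m <- preprocess_scan(frames)
  m$exposure_map[] <- exposure
  m
}

state_with <- function(name, value) {
  st <- c(temperature = 33, dissolved_oxygen = 0, pH = 6, sodium = 0,
          calcium = 0, glucose = 0)
  st[[name]] <- value
  do.call(biomarker_state, as.list(st))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
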