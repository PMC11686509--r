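test_that("biomarker states enforce the sensors' admissible ranges", {
  expect_error(biomarker_state(temperature = 50), "outside admissible range")
  expect_error(biomarker_state(dissolved_oxygen = -1), "outside admissible")
  clipped <- biomarker_state(temperature = 50, clip = TRUE)
  expect_equal(clipped[["temperature"]], 42)
  expect_equal(unname(unclass(healthy_state())),
               c(37, 6.5, 7.35, 145, 1.2, 3.3))
})

test_that("response curves honor the characterized sensitivities", {
  ch <- default_channels()
  # reference normalization, every channel
  for (nm in names(ch)) {
    ref <- ch[[nm]]$response$reference_condition
    expect_equal(evaluate_response(ch[[nm]], ref), 1, tolerance = 1e-12)
  }
  # quenched channels return I/I0 = 1 / (1 + slope * x)
  expect_equal(evaluate_response(ch$temperature, 42), 1 / (1 + 0.04 * 9),
               tolerance = 1e-12)
  expect_equal(evaluate_response(ch$dissolved_oxygen, 1), 1 / 1.38,
               tolerance = 1e-12)
  # printed fold changes survive the curve constructions
  expect_equal(evaluate_response(ch$pH, 8) / evaluate_response(ch$pH, 6), 5,
               tolerance = 1e-9)
  expect_equal(evaluate_response(ch$glucose, 5) / evaluate_response(ch$glucose, 1),
               4, tolerance = 1e-9)
  expect_equal(midpoint_slope(ch$pH$response), 2.624, tolerance = 1e-9)
  # out-of-range guard
  expect_error(evaluate_response(ch$pH, 9), "valid range")
  expect_equal(evaluate_response(ch$pH, 9, clip = TRUE),
               evaluate_response(ch$pH, 8))
})

test_that("responses are strictly monotone over their valid ranges", {
  ch <- default_channels()
  decreasing <- c("temperature", "dissolved_oxygen")
  for (nm in names(ch)) {
    rng <- ch[[nm]]$response$valid_range
    x <- seq(rng[1], rng[2], length.out = 41)
    r <- evaluate_response(ch[[nm]], x)
    if (nm %in% decreasing) expect_true(all(diff(r) < 0), label = nm)
    else expect_true(all(diff(r) > 0), label = nm)
  }
})

test_that("emitted frames follow the Lorentzian superposition model", {
  ch <- default_channels()
  ref <- state_with("pH", 6)
  f <- emit_spectrum(ch$pH, ref, exposure = 0, noise = noiseless_config())
  expect_equal(length(f$intensities), 460)
  expect_equal(which.max(f$intensities) - 1L, 34L)
  expect_equal(max(f$intensities), 1000, tolerance = 1e-9)
  # exposure = tau decays the peak by 1/e
  fb <- emit_spectrum(ch$pH, ref, exposure = ch$pH$tau,
                      noise = noiseless_config())
  expect_equal(max(fb$intensities), 1000 / exp(1), tolerance = 1e-9)
  # superposition: two-channel frame equals the sum of the single-channel
  # frames (noiseless, baseline-free)
  st <- biomarker_state(33, 2, 6.5, 0, 0, 0)
  f2 <- emit_spectrum(ch[c("pH", "dissolved_oxygen")], st,
                      noise = noiseless_config())
  fa <- emit_spectrum(ch$pH, st, noise = noiseless_config())
  fo <- emit_spectrum(ch$dissolved_oxygen, st, noise = noiseless_config())
  expect_equal(f2$intensities, fa$intensities + fo$intensities,
               tolerance = 1e-12)
  # three resolved maxima at the 405 nm channel pixels when narrow
  ch_narrow <- default_channels(peak_fwhm = 8)
  f3 <- emit_spectrum(ch_narrow[c("pH", "dissolved_oxygen", "glucose")],
                      biomarker_state(33, 4, 7, 0, 0, 3),
                      noise = noiseless_config())
  v <- f3$intensities
  locmax <- which(v > c(-Inf, head(v, -1)) & v >= c(tail(v, -1), -Inf)) - 1L
  locmax <- locmax[v[locmax + 1L] > 1]
  expect_length(locmax, 3)
  # superposed tails can pull each maximum by a pixel
  for (nominal in c(28, 34, 341))
    expect_lte(min(abs(locmax - nominal)), 1)
  expect_error(emit_spectrum(ch[c("pH", "sodium")], st,
                             noise = noiseless_config()),
               "share one excitation laser")
})

test_that("pulsed scans accumulate on-time and bleach consistently", {
  expect_error(pulse_schedule(on_s = 0), "positive")
  sc <- run_scan(healthy_state(), noise = noiseless_config())
  expect_equal(unname(sc$ledger), c(5, 5, 5))
  expect_equal(sort(names(sc$frames)), c("405", "488", "520"))
  # 720 cycles of 5 s pulses accumulate 3600 s per laser
  ledger <- new_exposure_ledger()
  for (i in 1:720)
    ledger <- ledger + pulse_schedule()$on_s
  expect_equal(unname(ledger), c(3600, 3600, 3600))
  # bleaching consistency: each film's emission at exposure t is its fresh
  # emission scaled by exp(-t / tau), exactly
  for (nm in biomarker_names()) {
    ch <- default_channels()[[nm]]
    st <- healthy_state()
    f0 <- emit_spectrum(ch, st, exposure = 0, noise = noiseless_config())
    ft <- emit_spectrum(ch, st, exposure = 12, noise = noiseless_config())
    expect_equal(ft$intensities, f0$intensities * exp(-12 / ch$tau),
                 tolerance = 1e-12, label = nm)
  }
})

test_that("calibration set generation is deterministic and covers the grid", {
  s <- generate_calibration_set(grid = list(temperature = seq(33, 42, 1)),
                                noise = noiseless_config(), seed = 3)
  expect_equal(length(s), 10L)
  # all other biomarkers at the reference condition
  expect_true(all(vapply(s$scans, function(x) x$state[["pH"]] == 6, logical(1))))
  expect_error(generate_calibration_set(grid = list()), "empty grid")
  expect_error(generate_calibration_set(grid = list(unknown = 1)), "unknown")
  # full 3-level factorial enumerates 3^6 states
  s3 <- generate_calibration_set(grid = lapply(default_calibration_grid(3),
                                               identity),
                                 noise = noiseless_config(), seed = 3)
  expect_equal(length(s3), 729L)
  # exposure is nondecreasing across the sweep
  ex <- vapply(s3$scans, `[[`, numeric(1), "exposure")
  expect_true(all(diff(ex) >= 0))
  expect_equal(max(ex), 20)
  # same seed, same data
  a <- generate_calibration_set(n = 5, seed = 11)
  b <- generate_calibration_set(n = 5, seed = 11)
  expect_identical(lapply(a$scans, function(x) x$frames[["405"]]$intensities),
                   lapply(b$scans, function(x) x$frames[["405"]]$intensities))
})

test_that("scenario presets encode the secondary-injury stage targets", {
  hyp <- scenario_preset("hypoxia")
  expect_equal(hyp$target[["temperature"]], 38)
  expect_equal(hyp$target[["dissolved_oxygen"]], 3.2)
  exc <- scenario_preset("excitotoxicity")
  expect_equal(exc$target[["pH"]], 6.5)
  expect_equal(exc$target[["sodium"]], 180)
  expect_equal(exc$target[["calcium"]], 3)
  hm <- scenario_preset("hypermetabolism")
  expect_equal(hm$target[["glucose"]], 1)
  expect_error(scenario_preset("zombie"), "unknown scenario preset")
  # zero-length transition gives a step change
  sc <- generate_scenario(list(scenario_stage("healthy", healthy_state(),
                                              120, 0),
                               scenario_preset("hypoxia", 120, 0)),
                          noise = noiseless_config())
  states <- vapply(sc$scans, function(x) x$state[["temperature"]], numeric(1))
  expect_setequal(unique(states), c(37, 38))
  # hypoxia labels hold the preset values in steady state
  expect_equal(tail(states, 1), 38)
})
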