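test_that("linear calibration fits recover exact lines", {
  T <- 33:42
  f <- fit_linear_ratio(T - 33, 1 + 0.04 * (T - 33))
  expect_equal(f$slope, 0.04, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  do <- 0:8
  expect_equal(fit_linear_ratio(do, 1 + 0.38 * do)$slope, 0.38,
               tolerance = 1e-12)
  # two points: interpolating line
  f2 <- fit_linear_ratio(c(1, 3), c(2, 8))
  expect_equal(f2$slope, 3)
  expect_equal(f2$r_squared, 1)
  expect_error(fit_linear_ratio(c(2, 2), c(1, 2)), "all concentrations equal")
})

test_that("four-parameter logistic fits are self-consistent", {
  cc <- seq(6, 8, length.out = 21)
  y <- 0.5 + (5 - 0.5) * plogis(2 * (cc - 7))
  f <- fit_logistic4(cc, y, midpoint_hint = 7)
  expect_rel(f$A, 0.5, 1e-6)
  expect_rel(f$B, 5, 1e-6)
  expect_rel(f$k, 2, 1e-6)
  expect_rel(f$c0, 7, 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # decreasing data encode orientation in the sign of k
  fdec <- fit_logistic4(cc, 5 - 4 * plogis(3 * (cc - 7)))
  expect_lt(fdec$k, 0)
  expect_error(fit_logistic4(1:3, c(1, 2, 3)), ">= 5")
})

test_that("curve inversion is the exact inverse of evaluation", {
  ch <- default_channels()
  expect_equal(invert_response(ch$temperature, 1), 33, tolerance = 1e-9)
  expect_equal(invert_response(ch$dissolved_oxygen, 1 / 1.38), 1,
               tolerance = 1e-9)
  set.seed(5)
  for (nm in names(ch)) {
    rng <- ch[[nm]]$response$valid_range
    cc <- runif(100, rng[1], rng[2])
    tol <- if (ch[[nm]]$response$family == "logistic4") 1e-6 else 1e-9
    back <- invert_response(ch[[nm]], evaluate_response(ch[[nm]], cc))
    expect_equal(back, cc, tolerance = tol, label = nm)
  }
  expect_error(invert_response(ch$dissolved_oxygen, 2), "attainable range")
})

test_that("the full spectral round trip recovers the configured sensitivities", {
  # quenched channels: OLS slope on I0/I
  cur <- measure_response_curve("temperature", 33:42)
  expect_rel(fit_linear_ratio(cur$value - 33, cur$quench_ratio)$slope,
             0.04, 0.02)
  cur <- measure_response_curve("dissolved_oxygen", 0:8)
  expect_rel(fit_linear_ratio(cur$value, cur$quench_ratio)$slope, 0.38, 0.02)
  # pH: logistic midpoint slope
  cur <- measure_response_curve("pH", seq(6, 8, 0.1))
  expect_rel(fit_logistic4(cur$value, cur$ratio, 7)$midpoint_slope, 2.624, 0.02)
  # sodium: linear slope per 10 mmol/L
  cur <- measure_response_curve("sodium", seq(0, 200, 20))
  expect_rel(10 * fit_linear_ratio(cur$value, cur$ratio)$slope, 0.064, 0.02)
  # calcium: straight-line slope over the physiological window
  cur <- measure_response_curve("calcium", seq(0, 2, 0.1))
  w <- cur$value >= 1.0 & cur$value <= 1.35
  expect_rel(fit_linear_ratio(cur$value[w], cur$ratio[w])$slope, 0.41, 0.02)
})

test_that("channel calibration fits reproduce the forward curves", {
  cal <- fx_get("cal_model", function() calibrate_channels())
  expect_true(all(unlist(cal$fit_r2) > 0.999))
  expect_equal(cal$responses$pH$parameters[["c0"]], 7, tolerance = 0.01)
  expect_equal(cal$responses$sodium$parameters[["slope"]], 0.0064,
               tolerance = 1e-4)
  expect_true(all(unlist(cal$reference_intensity) > 0))
})

test_that("two-point session calibration interpolates the standards exactly", {
  cal <- fx_get("cal_model", function() calibrate_channels())
  std <- default_standards()
  fvs <- lapply(std, function(st) {
    sc <- run_scan(st, noise = noiseless_config())
    photobleach_correct(extract_features(preprocess_scan(sc$frames)))
  })
  cal2 <- two_point_calibrate(fvs, std, cal)
  for (i in 1:2) {
    pr <- predict_classical(cal2, fvs[[i]])
    expect_equal(unclass(pr), unclass(std[[i]]), tolerance = 1e-8)
  }
  expect_error(two_point_calibrate(fvs, list(std$low, std$low), cal),
               "do not differ")
})

test_that("an unperturbed cross-talk-free instrument calibrates to unit gains", {
  ch0 <- default_channels(cross_temperature_coeff = 0)
  cal0 <- fx_get("cal_model0", function() calibrate_channels(ch0))
  std <- default_standards()
  char_features <- function(channels) lapply(std, function(st) {
    rows <- lapply(names(channels), function(nm)
      extract_features(single_channel_merged(channels[[nm]], st), channels[nm]))
    fv <- do.call(rbind, rows)
    attr(fv, "exposure") <- setNames(rep(0, 6), fv$channel)
    attr(fv, "corrected") <- FALSE
    class(fv) <- c("feature_vector", "data.frame")
    photobleach_correct(fv)
  })
  calI <- two_point_calibrate(char_features(ch0), std, cal0)
  gains <- vapply(calI$two_point_gains, `[[`, numeric(1), "gain")
  expect_equal(unname(gains), rep(1, 6), tolerance = 1e-6)
  # laser power drifted x1.3: gains pick up exactly the scale factor
  ch13 <- default_channels(base_amplitude = 1300, cross_temperature_coeff = 0)
  cal13 <- two_point_calibrate(char_features(ch13), std, cal0)
  gains13 <- vapply(cal13$two_point_gains, `[[`, numeric(1), "gain")
  expect_equal(unname(gains13), rep(1.3, 6), tolerance = 1e-6)
  # mid-range inversion through the gain-corrected linear channels
  mid <- biomarker_state(37, 4.5, 7.15, 100, 1.0, 3)
  fv_mid <- char_features_one <- local({
    rows <- lapply(names(ch13), function(nm)
      extract_features(single_channel_merged(ch13[[nm]], mid), ch13[nm]))
    fv <- do.call(rbind, rows)
    attr(fv, "exposure") <- setNames(rep(0, 6), fv$channel)
    attr(fv, "corrected") <- FALSE
    class(fv) <- c("feature_vector", "data.frame")
    photobleach_correct(fv)
  })
  pr <- predict_classical(cal13, fv_mid)
  for (nm in c("temperature", "dissolved_oxygen", "sodium"))
    expect_rel(pr[[nm]], mid[[nm]], 0.01)
})
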