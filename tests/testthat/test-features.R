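make_merged <- function(v405 = numeric(460), v488 = numeric(460),
                        v520 = numeric(460), exposure = 0) {
  m <- merge_frames(list(spectral_frame(405, v405, exposure),
                         spectral_frame(488, v488, exposure),
                         spectral_frame(520, v520, exposure)))
  m
}

test_that("peak features are exact on constructed peaks", {
  px <- 0:459
  A <- 700; w <- 24
  v <- A * (w / 2)^2 / ((px - 341)^2 + (w / 2)^2)
  fv <- extract_features(make_merged(v405 = v),
                         default_channels()["dissolved_oxygen"])
  expect_equal(fv$height, A, tolerance = 1e-9)
  expect_equal(fv$position, 341)
  expect_equal(fv$width, w, tolerance = 1 / w)  # within one pixel
  # flanking minima of an isolated peak sit at the segment edges, so the
  # prominence is the peak height above the higher edge tail
  expect_equal(fv$prominence, A - max(v[1], v[460]), tolerance = 1e-9)
  # symmetric triangle of height 2, half-width 10: trapezoid is exact
  tri <- pmax(0, 2 * (1 - abs(px - 341) / 10))
  fv <- extract_features(make_merged(v405 = tri),
                         default_channels()["dissolved_oxygen"])
  expect_equal(fv$area, 20, tolerance = 1e-12)
  expect_equal(fv$height, 2, tolerance = 1e-12)
})

test_that("overlapping pH/glucose peaks keep channel identity", {
  ch <- default_channels()
  st <- biomarker_state(33, 0, 6.5, 0, 0, 2)
  both <- emit_spectrum(ch[c("pH", "glucose")], st, noise = noiseless_config())
  ph_only <- emit_spectrum(ch$pH, st, noise = noiseless_config())
  glu_only <- emit_spectrum(ch$glucose, st, noise = noiseless_config())
  fv <- extract_features(make_merged(v405 = both$intensities),
                         ch[c("pH", "glucose")])
  fph <- extract_features(make_merged(v405 = ph_only$intensities), ch["pH"])
  fglu <- extract_features(make_merged(v405 = glu_only$intensities),
                           ch["glucose"])
  expect_lte(abs(fv$position[fv$channel == "pH"] - 34), 15)
  expect_lte(abs(fv$position[fv$channel == "glucose"] - 28), 15)
  # superposition inflates each fixed-index height above its single-film value
  expect_gt(fv$height[fv$channel == "pH"], fph$height)
  expect_gt(fv$height[fv$channel == "glucose"], fglu$height)
})

test_that("photobleach correction rescales intensity features only", {
  px <- 0:459
  v <- 1000 * 225 / ((px - 341)^2 + 225)
  m <- make_merged(v405 = v, exposure = 10)
  fv <- extract_features(m, default_channels()["dissolved_oxygen"])
  cv <- photobleach_correct(fv, c(dissolved_oxygen = 48.8))
  expect_equal(cv$height, fv$height * exp(10 / 48.8), tolerance = 1e-12)
  expect_equal(cv$area, fv$area * exp(10 / 48.8), tolerance = 1e-12)
  expect_equal(cv$prominence, fv$prominence * exp(10 / 48.8), tolerance = 1e-12)
  expect_identical(cv$width, fv$width)       # Lorentzian keeps its shape
  expect_identical(cv$position, fv$position)
  expect_error(photobleach_correct(cv, c(dissolved_oxygen = 48.8)),
               "already corrected")
  expect_error(photobleach_correct(fv, c(pH = 37)), "missing tau")
  # t = 0 leaves features unchanged; t = tau scales by e
  m0 <- make_merged(v405 = v, exposure = 0)
  f0 <- extract_features(m0, default_channels()["dissolved_oxygen"])
  c0 <- photobleach_correct(f0, c(dissolved_oxygen = 48.8))
  expect_equal(c0$height, f0$height, tolerance = 1e-12)
})

test_that("photobleach correction inverts the decay law for every channel", {
  ch <- default_channels()
  for (nm in names(ch)) {
    st <- state_with(nm, mean(ch[[nm]]$response$valid_range))
    h <- vapply(c(0, 25), function(t) {
      fv <- extract_features(single_channel_merged(ch[[nm]], st, exposure = t),
                             ch[nm])
      photobleach_correct(fv)$height[1L]
    }, numeric(1))
    expect_rel(h[2], h[1], 0.005)
  }
})

test_that("tau is recovered exactly from noiseless decays", {
  for (tau in c(10, 22, 48.8, 133.7, 200)) {
    t <- seq(0, 3 * tau, length.out = 25)
    fit <- fit_tau(t, 3 * exp(-t / tau))
    expect_rel(fit$tau, tau, 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
  # 1% multiplicative noise: within 5%
  set.seed(42)
  t <- seq(0, 180, 10)
  y <- 1000 * exp(-t / 48.8) * (1 + rnorm(length(t), 0, 0.01))
  expect_rel(fit_tau(t, y)$tau, 48.8, 0.05)
  expect_error(fit_tau(1:2, c(2, 1)), ">= 3")
  expect_error(fit_tau(1:5, c(1, 2, 3, -1, 2)), "positive")
  expect_error(fit_tau(1:5, rep(2, 5)), "degenerate")
})

test_that("Pearson selection matches a brute-force oracle", {
  set.seed(9)
  X <- matrix(rnorm(200 * 6), 200, dimnames = list(NULL, paste0("f", 1:6)))
  Y <- matrix(rnorm(200 * 2), 200, dimnames = list(NULL, c("a", "b")))
  sel <- pearson_select(X, Y, threshold = 0.5)
  brute <- outer(seq_len(ncol(X)), seq_len(ncol(Y)), Vectorize(function(i, j) {
    x <- X[, i]; y <- Y[, j]
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }))
  expect_equal(unname(sel$correlations), brute, tolerance = 1e-12)
  # a feature equal to a label is selected with r = 1
  X2 <- cbind(X, copy = Y[, "a"])
  sel2 <- pearson_select(X2, Y, threshold = 0.5)
  expect_true(sel2$mask[["copy"]])
  expect_equal(sel2$correlations["copy", "a"], 1, tolerance = 1e-12)
  # independent noise at n = 1000 is not selected at |r| >= 0.5
  set.seed(10)
  Xn <- matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "noise"))
  Yn <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_false(pearson_select(Xn, Yn, 0.5)$mask[["noise"]])
  # zero-variance feature: r = 0 with a warning
  Xc <- cbind(Xn, const = 1)
  expect_warning(selc <- pearson_select(Xc, Yn, 0.5), "zero-variance")
  expect_equal(unname(selc$correlations["const", ]), c(0, 0))
})

test_that("intensity features carry the correlation; isolated positions do not", {
  sel <- fx_noisy_selection()
  heights <- paste0(biomarker_names(), "_height")
  areas <- paste0(biomarker_names(), "_area")
  expect_true(all(sel$mask[heights]))
  expect_true(all(sel$mask[areas]))
  # isolated channels have immobile peaks: position carries no signal
  expect_false(any(sel$mask[c("temperature_position", "sodium_position",
                              "calcium_position")]))
})
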