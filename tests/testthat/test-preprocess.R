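px <- 0:459
lor <- function(c, A, w) A * (w / 2)^2 / ((px - c)^2 + (w / 2)^2)

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  expect_equal(denoise(rep(5, 460)), rep(5, 460), tolerance = 1e-10)
  line <- 2 + 0.3 * px
  sm <- denoise(line, window = 11, order = 3)
  interior <- 6:455
  expect_equal(sm[interior], line[interior], tolerance = 1e-9)
  expect_error(denoise(line, window = 10), "odd")
  expect_error(denoise(line, window = 11, order = 11), "order")
  # noise suppression on a Lorentzian: RMS error strictly below sigma
  set.seed(1)
  clean <- lor(341, 1000, 30)
  noisy <- clean + rnorm(460, 0, 5)
  sm <- denoise(noisy, window = 11, order = 3)
  expect_lt(sqrt(mean((sm - clean)^2)), 5)
})

test_that("baseline correction recovers known baselines and preserves peaks", {
  # zero in, zero out
  expect_equal(baseline_correct(numeric(460)), numeric(460))
  # pure slowly-decaying exponential: residual < 1% of amplitude
  bl <- 200 * exp(-0.002 * px)
  expect_lt(max(abs(baseline_correct(bl))), 2)
  # mid-segment Lorentzian on the simulator's default drift: height
  # recovered within 2% of the clean peak
  drift <- 150 * exp(-0.002 * px) + 20 + 0.02 * px - 1e-4 * px^2
  peak <- lor(341, 1000, 30)
  corr <- baseline_correct(peak + drift)
  expect_rel(corr[342], 1000, 0.02)
  # peak position unchanged
  expect_equal(which.max(corr), which.max(peak))
  expect_error(baseline_correct(bl, smoothness = -1), "smoothness")
  expect_error(baseline_correct(bl, asymmetry = 2, method = "als"), "asymmetry")
})

test_that("baseline correction is idempotent and scale-equivariant", {
  drift <- 150 * exp(-0.002 * px) + 20 + 0.02 * px - 1e-4 * px^2
  frames <- list(mid405 = lor(341, 1000, 30) + drift,
                 seg488 = lor(265, 1300, 30) + lor(424, 900, 30) + drift,
                 seg520 = lor(342, 1200, 30) + drift)
  for (nm in names(frames)) {
    c1 <- baseline_correct(frames[[nm]])
    c2 <- baseline_correct(c1)
    expect_lt(sqrt(mean((c2 - c1)^2)) / sqrt(mean(c1^2)), 0.005)
  }
  # exact scale equivariance preserves peak-height ratios
  y <- lor(28, 1394, 30) + lor(34, 1000, 30)
  expect_equal(baseline_correct(4 * y), 4 * baseline_correct(y),
               tolerance = 1e-12)
})

test_that("the fixed-asymmetry ALS variant is available and warns on non-convergence", {
  y <- lor(341, 1000, 30) + 100
  out <- baseline_correct(y, method = "als", iterations = 50)
  expect_equal(length(out), 460)
  expect_warning(baseline_correct(y, method = "als", iterations = 1),
                 "iterations")
})

test_that("standardization divides by the stored per-laser reference", {
  f <- spectral_frame(405, lor(34, 800, 30))
  s <- standardize(f, max(f$intensities))
  expect_equal(max(s$intensities), 1)
  s2 <- standardize(f, 2 * max(f$intensities))
  expect_equal(s2$intensities * 2, s$intensities)
  expect_error(standardize(f, -1), "calibration required")
  # sessions with different laser powers agree after standardization
  ch <- default_channels()
  ch17 <- default_channels(base_amplitude = 1700)
  st <- state_with("dissolved_oxygen", 3)
  f1 <- emit_spectrum(ch$dissolved_oxygen, st, noise = noiseless_config())
  f2 <- emit_spectrum(ch17$dissolved_oxygen, st, noise = noiseless_config())
  s1 <- standardize(f1, 1000)
  s2 <- standardize(f2, 1700)
  expect_equal(s1$intensities, s2$intensities, tolerance = 1e-12)
})

test_that("merging concatenates the three segments in fixed laser order", {
  fr <- lapply(c(520, 405, 488), function(l)
    spectral_frame(l, rep(l, 460), cumulative_on_time = l / 100))
  m <- merge_frames(fr)
  expect_equal(length(m$intensities), 1380)
  expect_equal(m$intensities[1], 405)
  expect_equal(m$intensities[461], 488)   # 488 pixel j -> 460 + j
  expect_equal(m$intensities[921], 520)
  expect_error(merge_frames(fr[1:2]), "one frame per laser")
  expect_error(merge_frames(c(fr, fr[1])), "one frame per laser")
  # unmerge round trip
  back <- merge_frames(unmerge(m))
  expect_equal(back$intensities, m$intensities)
  expect_equal(back$exposure_map, m$exposure_map)
})

test_that("labels attach idempotently and the pipeline records its steps", {
  fr <- lapply(c(405, 488, 520), function(l) spectral_frame(l, rep(1, 460)))
  m <- merge_frames(fr)
  expect_null(m$label)
  m <- set_label(m, healthy_state())
  expect_equal(m$label[["glucose"]], 3.3)
  m <- set_label(m, state_with("glucose", 1))  # relabel: last wins
  expect_equal(m$label[["glucose"]], 1)
  sc <- run_scan(healthy_state(), noise = noiseless_config())
  mm <- preprocess_scan(sc$frames, state = healthy_state())
  expect_equal(mm$provenance, c("denoise", "baseline_correct"))
})
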