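#' Noise and baseline configuration for the spectral simulator
#'
#' The simulated detector signal is peaks + baseline + noise, with
#' baseline(px) = `baseline_amplitude` * exp(-`baseline_decay` * px) +
#' polynomial(`baseline_poly_coeffs`, px) and i.i.d. Gaussian additive
#' noise of standard deviation `additive_sigma`. Setting every field to
#' zero yields a noiseless, baseline-free spectrum.
#'
#' @param additive_sigma Gaussian noise sd, intensity units.
#' @param baseline_amplitude amplitude of the exponential drift component.
#' @param baseline_decay per-pixel decay rate of the drift.
#' @param baseline_poly_coeffs polynomial coefficients (intercept first)
#'   evaluated on the 0-based pixel index.
#' @param seed optional integer seed; when set, dataset generators are
#'   deterministic.
#' @return object of class `noise_config`.
#' @export
noise_config <- function(additive_sigma = 2,
                         baseline_amplitude = 150,
                         baseline_decay = 0.002,
                         baseline_poly_coeffs = c(20, 0.02, -1e-4),
                         seed = NULL) {
  if (additive_sigma < 0) stop("additive_sigma must be >= 0", call. = FALSE)
  structure(list(additive_sigma = additive_sigma,
                 baseline_amplitude = baseline_amplitude,
                 baseline_decay = baseline_decay,
                 baseline_poly_coeffs = baseline_poly_coeffs,
                 seed = seed),
            class = "noise_config")
}

#' Noiseless, baseline-free simulator configuration
#' @return a [noise_config()] with all fields zero.
#' @export
noiseless_config <- function() noise_config(0, 0, 0, c(0, 0, 0), seed = NULL)

baseline_profile <- function(noise, n = segment_length()) {
  px <- seq_len(n) - 1
  b <- noise$baseline_amplitude * exp(-noise$baseline_decay * px)
  cf <- noise$baseline_poly_coeffs
  for (i in seq_along(cf)) b <- b + cf[i] * px^(i - 1)
  b
}

#' One laser's emission spectrum
#'
#' @param excitation_nm 405, 488 or 520.
#' @param intensities numeric vector of exactly 460 finite intensities.
#' @param cumulative_on_time accumulated on-time of this laser, seconds.
#' @param timestamp seconds since monitoring start.
#' @param exposure_units accumulated exposure in the abstract units the
#'   photobleaching constants tau are expressed in (defaults to
#'   `cumulative_on_time`; pulsed operation bleaches far slower than
#'   wall-clock seconds suggest, see [pulse_schedule()]).
#' @return object of class `spectral_frame`.
#' @export
spectral_frame <- function(excitation_nm, intensities, cumulative_on_time = 0,
                           timestamp = 0, exposure_units = cumulative_on_time) {
  if (length(intensities) != segment_length())
    stop("spectral_frame: intensities must have length ", segment_length(),
         " (got ", length(intensities), ")", call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("spectral_frame: intensities must be finite", call. = FALSE)
  if (!excitation_nm %in% c(405, 488, 520))
    stop("spectral_frame: unknown laser ", excitation_nm, call. = FALSE)
  structure(list(excitation_nm = excitation_nm,
                 intensities = as.numeric(intensities),
                 cumulative_on_time = cumulative_on_time,
                 exposure_units = exposure_units,
                 timestamp = timestamp),
            class = "spectral_frame")
}

#' @export
print.spectral_frame <- function(x, ...) {
  cat(sprintf("<spectral_frame> %d nm  max %.4g @px %d  exposure %.4g  t %.4g s\n",
              x$excitation_nm, max(x$intensities),
              which.max(x$intensities) - 1L, x$cumulative_on_time, x$timestamp))
  invisible(x)
}

lorentzian <- function(px, center, amplitude, fwhm) {
  g2 <- (fwhm / 2)^2
  amplitude * g2 / ((px - center)^2 + g2)
}

#' Simulate one laser's emission spectrum
#'
#' Each channel contributes a Lorentzian peak centered at its within-segment
#' pixel, with amplitude
#' `base_amplitude * (I/I0)(state) * exp(-exposure / tau) * exp(-q (T - 33))`.
#' Peaks superpose additively; the baseline and Gaussian noise of `noise`
#' are then added (drawn from the current RNG stream).
#'
#' @param channels list of [sensor_channel()]s sharing one excitation laser.
#' @param state a [biomarker_state()].
#' @param exposure this laser's cumulative on-time, exposure-time units.
#' @param noise a [noise_config()].
#' @param timestamp seconds since monitoring start.
#' @param clip clamp out-of-range state values.
#' @return a [spectral_frame()].
#' @examples
#' ch <- default_channels()
#' f <- emit_spectrum(ch[c("pH", "dissolved_oxygen", "glucose")],
#'                    healthy_state(), exposure = 0, noise = noiseless_config())
#' @export
emit_spectrum <- function(channels, state, exposure = 0,
                          noise = noiseless_config(), timestamp = 0,
                          clip = FALSE) {
  if (inherits(channels, "sensor_channel")) channels <- list(channels)
  lasers <- unique(vapply(channels, `[[`, numeric(1), "excitation_nm"))
  if (length(lasers) != 1L)
    stop("emit_spectrum: all channels must share one excitation laser (got ",
         paste(lasers, collapse = ", "), ")", call. = FALSE)
  if (exposure < 0) stop("emit_spectrum: exposure must be >= 0", call. = FALSE)
  state <- as_biomarker_state(state, clip = clip)
  px <- seq_len(segment_length()) - 1
  y <- numeric(segment_length())
  for (ch in channels) {
    amp <- ch$base_amplitude *
      evaluate_response(ch, state, clip = clip) *
      exp(-exposure / ch$tau) *
      exp(-ch$cross_temperature_coeff * (state[["temperature"]] - 33))
    y <- y + lorentzian(px, ch$merged_peak_index %% segment_length(), amp, ch$peak_fwhm)
  }
  y <- y + baseline_profile(noise)
  if (noise$additive_sigma > 0)
    y <- y + rnorm(segment_length(), 0, noise$additive_sigma)
  spectral_frame(lasers, pmax(y, 0), cumulative_on_time = exposure,
                 timestamp = timestamp)
}

#' Pulsed excitation schedule
#'
#' The instrument fires the three lasers sequentially in pulse cycles,
#' 5 s on and 5 s off by default, in the order 405, 488, 520 nm; one full
#' scan therefore takes 30 s.
#'
#' @param on_s on-duration per laser, seconds.
#' @param off_s off-duration per laser, seconds.
#' @param lasers firing order.
#' @param exposure_units_per_s conversion from seconds of laser on-time to
#'   the abstract exposure-time units the photobleaching constants tau are
#'   expressed in. The default 0.01 encodes the observation that pulsed
#'   excitation (5 s on / 5 s off) bleaches the films roughly two orders
#'   of magnitude slower than the continuous-exposure decay the tau
#'   constants were fitted to.
#' @return object of class `pulse_schedule`.
#' @export
pulse_schedule <- function(on_s = 5, off_s = 5, lasers = c(405, 488, 520),
                           exposure_units_per_s = 0.01) {
  if (on_s <= 0 || off_s <= 0)
    stop("pulse_schedule: on_s and off_s must be positive", call. = FALSE)
  if (exposure_units_per_s <= 0)
    stop("pulse_schedule: exposure_units_per_s must be positive", call. = FALSE)
  structure(list(on_s = on_s, off_s = off_s, lasers = lasers,
                 exposure_units_per_s = exposure_units_per_s),
            class = "pulse_schedule")
}

#' Duration of one full scan cycle, seconds
#' @param schedule a [pulse_schedule()].
#' @export
scan_period <- function(schedule = pulse_schedule()) {
  length(schedule$lasers) * (schedule$on_s + schedule$off_s)
}

#' Empty exposure ledger
#' @return named numeric vector of zero cumulative on-times per laser.
#' @export
new_exposure_ledger <- function() c("405" = 0, "488" = 0, "520" = 0)

#' Run one multiplexed scan
#'
#' Fires the three lasers in sequence, capturing one [spectral_frame()] per
#' laser at the end of its on-pulse; each laser's cumulative on-time grows
#' by the pulse duration (converted to exposure units) and the timestamp
#' advances by the full cycle length.
#'
#' @param state a [biomarker_state()].
#' @param schedule a [pulse_schedule()].
#' @param noise a [noise_config()].
#' @param ledger exposure ledger from the previous scan
#'   ([new_exposure_ledger()] for a cold start).
#' @param channels channel set, default [default_channels()].
#' @param timestamp scan start time, seconds.
#' @param clip clamp out-of-range state values.
#' @return list with `frames` (named list of three frames), `ledger`
#'   (updated), and `timestamp` (end of scan).
#' @export
run_scan <- function(state, schedule = pulse_schedule(),
                     noise = noiseless_config(),
                     ledger = new_exposure_ledger(),
                     channels = default_channels(),
                     timestamp = 0, clip = FALSE) {
  assign <- laser_assignment()
  frames <- list()
  t <- timestamp
  for (nm in as.character(schedule$lasers)) {
    ledger[[nm]] <- ledger[[nm]] + schedule$on_s   # seconds of on-time
    t <- t + schedule$on_s
    eu <- ledger[[nm]] * schedule$exposure_units_per_s
    f <- emit_spectrum(channels[assign[[nm]]], state, exposure = eu,
                       noise = noise, timestamp = t, clip = clip)
    f$cumulative_on_time <- ledger[[nm]]
    f$exposure_units <- eu
    frames[[nm]] <- f
    t <- t + schedule$off_s
  }
  list(frames = frames, ledger = ledger, timestamp = t)
}

reference_state <- function() {
  biomarker_state(temperature = 33, dissolved_oxygen = 0, pH = 6,
                  sodium = 0, calcium = 0, glucose = 0)
}

#' Default factorial calibration grid
#'
#' Evenly spaced levels per biomarker spanning the range bracketed by the
#' two calibration standard buffers (see [default_standards()]).
#'
#' @param levels number of levels per biomarker.
#' @return named list of level vectors.
#' @export
default_calibration_grid <- function(levels = 5) {
  anchors <- default_standards()
  lapply(setNames(biomarker_names(), biomarker_names()), function(nm)
    seq(anchors$low[[nm]], anchors$high[[nm]], length.out = levels))
}

#' Generate a labeled calibration dataset
#'
#' Sweeps the factorial product of the per-biomarker grids (biomarkers not
#' in `grid` stay at the channel reference condition), emitting one
#' three-frame scan per grid point and replicate. Exposure accumulates
#' linearly from 0 to `max_exposure` across the sweep, so photobleaching is
#' present in the generated features. Deterministic given `seed`.
#'
#' @param grid named list of analyte level vectors, e.g.
#'   `list(temperature = 33:42)`; defaults to the full six-channel
#'   factorial of [default_calibration_grid()].
#' @param replicates scans per grid point.
#' @param noise a [noise_config()].
#' @param seed integer seed (overrides `noise$seed`).
#' @param channels channel set.
#' @param max_exposure total accumulated exposure (units of tau) reached at
#'   the end of the sweep; all three lasers share the same exposure value.
#' @param n if non-NULL, randomly subsample the factorial to `n` scans
#'   (before replication), as when a full factorial is too large to sweep.
#' @param shuffle randomize sweep order so exposure is not confounded with
#'   the grid ordering.
#' @return object of class `scan_set`: a list of scans, each with `frames`
#'   (named list of three raw [spectral_frame()]s), `state` (the true
#'   label) and `exposure`.
#' @export
generate_calibration_set <- function(grid = default_calibration_grid(),
                                     replicates = 1,
                                     noise = noise_config(),
                                     seed = noise$seed,
                                     channels = default_channels(),
                                     max_exposure = 20,
                                     n = NULL, shuffle = TRUE) {
  if (!length(grid) || any(!lengths(grid)))
    stop("generate_calibration_set: empty grid", call. = FALSE)
  bad <- setdiff(names(grid), biomarker_names())
  if (length(bad))
    stop("generate_calibration_set: unknown biomarkers in grid: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ref <- reference_state()
  pts <- do.call(expand.grid, c(grid, list(KEEP.OUT.ATTRS = FALSE)))
  if (!is.null(n) && n < nrow(pts))
    pts <- pts[sample.int(nrow(pts), n), , drop = FALSE]
  pts <- pts[rep(seq_len(nrow(pts)), each = replicates), , drop = FALSE]
  if (shuffle) pts <- pts[sample.int(nrow(pts)), , drop = FALSE]
  m <- nrow(pts)
  expo <- if (m > 1) seq(0, max_exposure, length.out = m) else 0
  assign <- laser_assignment()
  scans <- vector("list", m)
  for (i in seq_len(m)) {
    st <- unclass(ref)
    for (nm in names(grid)) st[[nm]] <- pts[i, nm]
    st <- as_biomarker_state(st)
    frames <- lapply(setNames(names(assign), names(assign)), function(l)
      emit_spectrum(channels[assign[[l]]], st, exposure = expo[i],
                    noise = noise, timestamp = (i - 1) * 30))
    scans[[i]] <- list(frames = frames, state = st, exposure = expo[i])
  }
  structure(list(scans = scans, channels = channels,
                 meta = list(seed = seed, max_exposure = max_exposure,
                             grid = grid, replicates = replicates)),
            class = "scan_set")
}

#' @export
length.scan_set <- function(x) length(x$scans)

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf("<scan_set> %d scans, exposure 0..%g units\n",
              length(x), x$meta$max_exposure))
  invisible(x)
}

# ---- scenarios --------------------------------------------------------------

#' One stage of a monitoring scenario
#'
#' @param name stage name (free text, or a preset name for
#'   [scenario_preset()]).
#' @param target a [biomarker_state()] held during the stage.
#' @param duration_s stage duration, seconds (>= 0).
#' @param transition_s ramp time from the previous stage's state to
#'   `target` (>= 0; 0 gives a step change).
#' @return object of class `scenario_stage`.
#' @export
scenario_stage <- function(name, target, duration_s, transition_s = 60) {
  if (duration_s < 0 || transition_s < 0)
    stop("scenario_stage: durations must be >= 0", call. = FALSE)
  structure(list(name = name, target = as_biomarker_state(target),
                 duration_s = duration_s, transition_s = transition_s),
            class = "scenario_stage")
}

#' Built-in secondary-injury stage presets
#'
#' Stage targets for the monitored brain-injury complications: hypoxia
#' (38 deg C, 3.2 mg/L DO), hypermetabolism (39 deg C, 3.8 mg/L DO,
#' 1 mmol/L glucose), excitotoxicity (pH 6.5, 180 mmol/L Na+, 3 mmol/L
#' Ca2+), with unlisted biomarkers at the healthy defaults, plus the
#' `healthy` baseline itself.
#'
#' @param name preset name.
#' @param duration_s,transition_s passed to [scenario_stage()].
#' @return a [scenario_stage()].
#' @export
scenario_preset <- function(name, duration_s = 600, transition_s = 60) {
  h <- unclass(healthy_state())
  tgt <- switch(name,
    healthy         = h,
    hypoxia         = replace(h, c("temperature", "dissolved_oxygen"), c(38, 3.2)),
    hypermetabolism = replace(h, c("temperature", "dissolved_oxygen", "glucose"),
                              c(39, 3.8, 1)),
    excitotoxicity  = replace(h, c("pH", "sodium", "calcium"), c(6.5, 180, 3)),
    stop("unknown scenario preset: ", name, call. = FALSE))
  scenario_stage(name, as_biomarker_state(tgt), duration_s, transition_s)
}

scenario_state_at <- function(stages, t) {
  # piecewise: each stage ramps linearly from the previous target over
  # transition_s, then holds until its duration elapses
  prev <- unclass(healthy_state())
  t0 <- 0
  for (st in stages) {
    t1 <- t0 + st$duration_s
    if (t < t1 || identical(st, stages[[length(stages)]])) {
      tgt <- unclass(st$target)
      if (st$transition_s > 0 && t < t0 + st$transition_s) {
        a <- max(0, (t - t0)) / st$transition_s
        return(as_biomarker_state(prev + a * (tgt - prev)))
      }
      return(st$target)
    }
    prev <- unclass(st$target)
    t0 <- t1
  }
  as_biomarker_state(prev)
}

#' Simulate a staged monitoring scenario
#'
#' The biomarker state follows the stage sequence (linear ramp over each
#' stage's transition time, then hold); one multiplexed scan is taken per
#' scan period.
#'
#' @param stages list of [scenario_stage()]s, or preset names understood by
#'   [scenario_preset()].
#' @param schedule a [pulse_schedule()]; the scan period is its cycle
#'   length.
#' @param noise a [noise_config()].
#' @param seed optional seed.
#' @param channels channel set.
#' @param clip clamp out-of-range trajectory values (the presets stay in
#'   range).
#' @return a `scan_set` whose scans additionally carry `stage` (name) and
#'   `time_s`.
#' @export
generate_scenario <- function(stages, schedule = pulse_schedule(),
                              noise = noiseless_config(), seed = noise$seed,
                              channels = default_channels(), clip = FALSE) {
  if (is.character(stages)) stages <- lapply(stages, scenario_preset)
  if (!length(stages)) stop("generate_scenario: no stages", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  period <- scan_period(schedule)
  total <- sum(vapply(stages, `[[`, numeric(1), "duration_s"))
  times <- seq(0, total - 1e-9, by = period)
  ledger <- new_exposure_ledger()
  bounds <- cumsum(vapply(stages, `[[`, numeric(1), "duration_s"))
  scans <- vector("list", length(times))
  for (i in seq_along(times)) {
    st <- scenario_state_at(stages, times[i])
    sc <- run_scan(st, schedule, noise, ledger, channels,
                   timestamp = times[i], clip = clip)
    ledger <- sc$ledger
    k <- which(times[i] < bounds)[1]
    scans[[i]] <- list(frames = sc$frames, state = st,
                       exposure = unname(ledger[["405"]]),
                       stage = stages[[k]]$name, time_s = times[i])
  }
  structure(list(scans = scans, channels = channels,
                 meta = list(stages = stages, schedule = schedule, seed = seed,
                             max_exposure = unname(ledger[["405"]]))),
            class = "scan_set")
}
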