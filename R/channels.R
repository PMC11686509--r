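#' Sensor channel descriptors
#'
#' A `sensor_channel` binds one fluorescent sensing film to its excitation
#' laser, its peak location in the merged 1380-point measurement vector,
#' its calibration response curve, its photobleaching time constant and its
#' peak geometry.
#'
#' Laser-to-sensor assignment is fixed by the instrument: the 405 nm laser
#' excites the pH, dissolved-oxygen and glucose films; the 488 nm laser the
#' sodium and temperature films; the 520 nm laser the calcium film. The
#' merged measurement vector concatenates the three 460-pixel spectra in
#' the order 405 | 488 | 520, and the six peaks sit at merged indices 34
#' (pH), 28 (glucose), 341 (DO), 725 (Na+), 884 (temperature) and 1262
#' (Ca2+), 0-based.
#'
#' @param name one of `"pH"`, `"glucose"`, `"DO"`, `"sodium"`,
#'   `"temperature"`, `"calcium"` (`"DO"` is an alias for
#'   `"dissolved_oxygen"` in channel naming).
#' @param excitation_nm excitation wavelength, one of 405, 488, 520.
#' @param merged_peak_index 0-based peak index in the merged vector; must
#'   lie in its laser's segment.
#' @param response a [response_params()] object.
#' @param tau photobleaching time constant, in exposure-time units.
#' @param peak_fwhm Lorentzian full width at half maximum, pixels.
#' @param base_amplitude emitted peak amplitude at the reference condition,
#'   fresh film, arbitrary intensity units.
#' @param cross_temperature_coeff temperature cross-quench coefficient q
#'   (per deg C): every channel's amplitude is multiplied by
#'   exp(-q (T - 33)). Zero for the temperature channel itself, whose
#'   response curve already carries the temperature dependence.
#' @return object of class `sensor_channel`.
#' @export
sensor_channel <- function(name, excitation_nm, merged_peak_index, response,
                           tau, peak_fwhm = 30, base_amplitude = 1000,
                           cross_temperature_coeff = 0.005) {
  lasers <- laser_assignment()
  if (!name %in% unlist(lasers))
    stop("unknown channel name: ", name, call. = FALSE)
  if (!excitation_nm %in% c(405, 488, 520))
    stop("excitation_nm must be 405, 488 or 520", call. = FALSE)
  if (!name %in% lasers[[as.character(excitation_nm)]])
    stop(sprintf("channel '%s' is not excited by the %d nm laser", name, excitation_nm),
         call. = FALSE)
  seg <- laser_segment(excitation_nm)
  if (merged_peak_index < seg[1] || merged_peak_index > seg[2])
    stop(sprintf("merged_peak_index %d outside the %d nm segment [%d, %d]",
                 merged_peak_index, excitation_nm, seg[1], seg[2]), call. = FALSE)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (peak_fwhm <= 0) stop("peak_fwhm must be positive", call. = FALSE)
  if (cross_temperature_coeff < 0)
    stop("cross_temperature_coeff must be >= 0", call. = FALSE)
  structure(list(name = name, excitation_nm = excitation_nm,
                 merged_peak_index = as.integer(merged_peak_index),
                 response = response, tau = tau, peak_fwhm = peak_fwhm,
                 base_amplitude = base_amplitude,
                 cross_temperature_coeff = cross_temperature_coeff),
            class = "sensor_channel")
}

#' @export
print.sensor_channel <- function(x, ...) {
  cat(sprintf("<sensor_channel> %s  laser %d nm  peak @%d  tau %.4g  fwhm %g px\n",
              x$name, x$excitation_nm, x$merged_peak_index, x$tau, x$peak_fwhm))
  invisible(x)
}

#' Fixed laser-to-sensor assignment
#' @return named list: laser wavelength (as character) -> channel names.
#' @export
laser_assignment <- function() {
  list("405" = c("pH", "dissolved_oxygen", "glucose"),
       "488" = c("sodium", "temperature"),
       "520" = c("calcium"))
}

#' Pixel span of one laser's segment in the merged vector
#' @param excitation_nm 405, 488 or 520.
#' @return `c(first, last)` 0-based merged indices.
#' @export
laser_segment <- function(excitation_nm) {
  i <- match(as.character(excitation_nm), c("405", "488", "520"))
  if (is.na(i)) stop("unknown laser: ", excitation_nm, call. = FALSE)
  c((i - 1L) * 460L, i * 460L - 1L)
}

#' Pixels per laser segment and merged vector length
#' @export
segment_length <- function() 460L

#' Default photobleaching time constants
#'
#' Per-sensor exponential decay constants (exposure-time units) obtained
#' from least-squares fits to photostability traces: temperature 51.13,
#' DO 48.8, pH 37.0, Na+ 22.0, Ca2+ 38.0, glucose 133.7.
#'
#' @return named numeric vector.
#' @export
default_taus <- function() {
  c(temperature = 51.13, dissolved_oxygen = 48.8, pH = 37.0,
    sodium = 22.0, calcium = 38.0, glucose = 133.7)
}

#' Default merged peak indices (0-based)
#' @return named integer vector.
#' @export
default_peak_indices <- function() {
  c(pH = 34L, glucose = 28L, dissolved_oxygen = 341L,
    sodium = 725L, temperature = 884L, calcium = 1262L)
}

#' The default six-channel sensor set
#'
#' Builds the six [sensor_channel()] descriptors with the characterized
#' response curves, default photobleaching constants, Lorentzian FWHM 30
#' pixels and base amplitude 1000.
#'
#' @param peak_fwhm Lorentzian FWHM in pixels, recycled over channels.
#' @param base_amplitude reference peak amplitude, recycled over channels.
#' @param cross_temperature_coeff temperature cross-quench per deg C applied
#'   to the non-temperature channels.
#' @return named list of six `sensor_channel` objects, in
#'   [biomarker_names()] order.
#' @export
default_channels <- function(peak_fwhm = 30, base_amplitude = 1000,
                             cross_temperature_coeff = 0.005) {
  nms <- biomarker_names()
  fw <- rep_len(peak_fwhm, 6L); ba <- rep_len(base_amplitude, 6L)
  idx <- default_peak_indices(); taus <- default_taus()
  ex <- c(temperature = 488, dissolved_oxygen = 405, pH = 405,
          sodium = 488, calcium = 520, glucose = 405)
  ch <- lapply(seq_along(nms), function(i) {
    nm <- nms[i]
    sensor_channel(nm, ex[[nm]], idx[[nm]], default_response(nm), taus[[nm]],
                   peak_fwhm = fw[i], base_amplitude = ba[i],
                   cross_temperature_coeff =
                     if (nm == "temperature") 0 else cross_temperature_coeff)
  })
  setNames(ch, nms)
}

#' Evaluate a channel's emission response at a biomarker state
#'
#' Returns the relative emitted intensity I/I0 of the channel's film at the
#' given state: 1 at the reference condition, decreasing with analyte for
#' the quenched channels (temperature, DO), increasing for pH, Na+, Ca2+
#' and glucose. Only the channel's own analyte enters; the temperature
#' cross-quench is a separate multiplicative factor applied by
#' [emit_spectrum()].
#'
#' @param channel a [sensor_channel()].
#' @param state a [biomarker_state()] (or value(s) of the channel's analyte).
#' @param clip clamp out-of-range analyte values to the curve's valid range.
#' @return I/I0 ratio(s).
#' @examples
#' ch <- default_channels()
#' evaluate_response(ch$temperature, biomarker_state(temperature = 33)) # 1
#' evaluate_response(ch$dissolved_oxygen, 1)  # 1 / 1.38
#' @export
evaluate_response <- function(channel, state, clip = FALSE) {
  x <- if (inherits(state, "biomarker_state")) state[[channel$name]] else as.numeric(state)
  rng <- channel$response$valid_range
  out <- x < rng[1] - 1e-12 | x > rng[2] + 1e-12
  if (any(out)) {
    if (!clip)
      stop(sprintf("evaluate_response: %s value outside valid range [%g, %g] (use clip = TRUE)",
                   channel$name, rng[1], rng[2]), call. = FALSE)
    x <- pmin(pmax(x, rng[1]), rng[2])
  }
  response_ratio(channel$response, x)
}

#' Invert a channel's response: emission ratio to concentration
#'
#' The classical (non-ML) readout path: given a measured emission ratio
#' I/I0, return the unique analyte value on the channel's calibration
#' curve.
#'
#' @param channel a [sensor_channel()], or a name in [biomarker_names()].
#' @param ratio measured I/I0 ratio(s).
#' @return analyte value(s) in the channel's units.
#' @examples
#' ch <- default_channels()
#' invert_response(ch$temperature, 1)           # 33 degC
#' invert_response(ch$dissolved_oxygen, 1/1.38) # 1 mg/L
#' @export
invert_response <- function(channel, ratio) {
  if (is.character(channel)) channel <- default_channels()[[channel]]
  invert_ratio(channel$response, ratio)
}
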