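#' Ordinary least-squares fit of a linear calibration line
#'
#' Fits ratio = intercept + slope * concentration. Used for the
#' Stern-Volmer channels (temperature, DO, on the I0/I scale) and the
#' sodium channel (I/I0 scale).
#'
#' @param concentrations analyte values (>= 2 distinct).
#' @param ratios measured intensity ratios.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
fit_linear_ratio <- function(concentrations, ratios) {
  if (length(concentrations) != length(ratios) || length(concentrations) < 2)
    stop("fit_linear_ratio: need >= 2 points", call. = FALSE)
  if (sd(concentrations) == 0)
    stop("fit_linear_ratio: all concentrations equal, cannot fit", call. = FALSE)
  f <- lsfit(concentrations, ratios)
  pred <- f$coefficients[1L] + f$coefficients[2L] * concentrations
  ss_tot <- sum((ratios - mean(ratios))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum((ratios - pred)^2) / ss_tot
  list(slope = unname(f$coefficients[2L]),
       intercept = unname(f$coefficients[1L]), r_squared = r2)
}

#' Four-parameter logistic calibration fit
#'
#' Nonlinear least squares on R(c) = A + (B - A) / (1 + exp(-k (c - c0))),
#' initialized from the data range and `midpoint_hint`. Decreasing data
#' yield k < 0 (orientation lives in the sign of k).
#'
#' @param concentrations analyte values (>= 5, spanning the transition).
#' @param ratios measured intensity ratios.
#' @param midpoint_hint starting value for the midpoint c0 (default: value
#'   at the half-range crossing).
#' @return list with `A`, `B`, `k`, `c0`, `r_squared` and
#'   `midpoint_slope` = (B - A) k / 4.
#' @export
fit_logistic4 <- function(concentrations, ratios, midpoint_hint = NULL) {
  if (length(concentrations) != length(ratios) || length(concentrations) < 5)
    stop("fit_logistic4: need >= 5 points spanning the transition", call. = FALSE)
  inc <- cor(concentrations, ratios) >= 0
  if (is.null(midpoint_hint)) {
    half <- (min(ratios) + max(ratios)) / 2
    midpoint_hint <- approx(ratios, concentrations, xout = half,
                            ties = mean)$y
    if (is.na(midpoint_hint)) midpoint_hint <- median(concentrations)
  }
  span <- diff(range(concentrations))
  start <- list(A = if (inc) min(ratios) else max(ratios),
                B = if (inc) max(ratios) else min(ratios),
                k = (if (inc) 1 else -1) * 4 / span,
                c0 = midpoint_hint)
  df <- data.frame(c = concentrations, y = ratios)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A + (B - A) / (1 + exp(-k * (c - c0))), data = df,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("fit_logistic4: did not converge (", conditionMessage(e),
           "); starting values were A=", signif(start$A, 4), " B=",
           signif(start$B, 4), " k=", signif(start$k, 4), " c0=",
           signif(start$c0, 4), call. = FALSE))
  cf <- as.list(coef(fit))
  pred <- predict(fit)
  ss_tot <- sum((ratios - mean(ratios))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum((ratios - pred)^2) / ss_tot
  c(cf, list(r_squared = r2, midpoint_slope = (cf$B - cf$A) * cf$k / 4))
}

zero_frame <- function(excitation_nm, timestamp = 0) {
  spectral_frame(excitation_nm, numeric(segment_length()), 0, timestamp)
}

#' Measure a channel's response curve through the full spectral round trip
#'
#' The in-silico analogue of a single-sensor characterization sweep:
#' noiseless single-channel frames are generated at each analyte value
#' (all other biomarkers at their reference condition, exposure 0), pushed
#' through denoising and baseline correction, and the peak height at the
#' channel's fixed index is read out. Ratios are reported relative to the
#' height at the channel's reference condition.
#'
#' @param channel a [sensor_channel()] (or a name in [biomarker_names()]).
#' @param values analyte sweep values.
#' @param channels full channel set (used to resolve a channel name).
#' @param ... passed to [preprocess_scan()].
#' @return data.frame with `value`, `height`, `ratio` (I/I0) and
#'   `quench_ratio` (I0/I).
#' @export
measure_response_curve <- function(channel, values,
                                   channels = default_channels(), ...) {
  if (is.character(channel)) channel <- channels[[channel]]
  ref <- channel$response$reference_condition
  sweep <- unique(c(ref, values))
  heights <- vapply(sweep, function(v) {
    st <- unclass(reference_state())
    st[[channel$name]] <- v
    fr <- emit_spectrum(list(channel), as_biomarker_state(st), exposure = 0,
                        noise = noiseless_config())
    frames <- lapply(c(405, 488, 520), function(l)
      if (l == channel$excitation_nm) fr else zero_frame(l))
    m <- preprocess_scan(frames, ...)
    fv <- extract_features(m, channels = list(channel))
    fv$height[1L]
  }, numeric(1))
  h_ref <- heights[1L]
  keep <- match(values, sweep)
  data.frame(value = values, height = heights[keep],
             ratio = heights[keep] / h_ref,
             quench_ratio = h_ref / heights[keep])
}

#' Fitted calibration state of the instrument
#'
#' Bundles, per channel: the fitted [response_params()], the fit R-squared,
#' the reference intensity (pipeline peak height at the reference
#' condition), and the two-point session gains; plus per-laser reference
#' intensities for [standardize()].
#'
#' @param responses named list of fitted `response_params` per channel.
#' @param fit_r2 named numeric, fit R-squared per channel.
#' @param reference_intensity named numeric per channel.
#' @param two_point_gains named list per channel: `gain` (multiplicative,
#'   1 = nominal) and `offset` (intensity units).
#' @param laser_references named numeric per laser for [standardize()].
#' @param taus per-channel photobleaching constants in effect.
#' @param source free-text dataset identifier.
#' @return object of class `calibration_model`.
#' @export
calibration_model <- function(responses, fit_r2, reference_intensity,
                              two_point_gains = NULL,
                              laser_references = NULL,
                              taus = default_taus(), source = "simulated") {
  if (is.null(two_point_gains))
    two_point_gains <- lapply(setNames(names(responses), names(responses)),
                              function(.) list(gain = 1, offset = 0))
  if (any(vapply(two_point_gains, function(g) g$gain <= 0, logical(1))))
    stop("calibration_model: gains must be positive", call. = FALSE)
  structure(list(responses = responses, fit_r2 = fit_r2,
                 reference_intensity = reference_intensity,
                 two_point_gains = two_point_gains,
                 laser_references = laser_references, taus = taus,
                 created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 source = source),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>", x$source, "fitted", x$created_at, "\n")
  for (nm in names(x$responses))
    cat(sprintf("  %-17s %-12s R2 %.4f  ref %.4g  gain %.4g\n", nm,
                x$responses[[nm]]$family, x$fit_r2[[nm]],
                x$reference_intensity[[nm]], x$two_point_gains[[nm]]$gain))
  invisible(x)
}

#' Fit the full calibration model from simulated characterization sweeps
#'
#' Runs [measure_response_curve()] for every channel over `points` evenly
#' spaced values of its valid range and fits the channel's curve family:
#' ordinary least squares on I0/I for the quenched channels, on I/I0 for
#' sodium, and a four-parameter logistic for pH, glucose and calcium.
#'
#' @param channels channel set.
#' @param points sweep points per channel.
#' @param ... passed to [measure_response_curve()].
#' @return a [calibration_model()].
#' @export
calibrate_channels <- function(channels = default_channels(), points = 11, ...) {
  responses <- list(); r2 <- c(); refint <- c(); laser_ref <- list()
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    rng <- ch$response$valid_range
    vals <- seq(rng[1], rng[2], length.out = points)
    cur <- measure_response_curve(ch, vals, channels = channels, ...)
    fam <- ch$response$family
    if (fam == "stern_volmer") {
      f <- fit_linear_ratio(cur$value - ch$response$reference_condition,
                            cur$quench_ratio)
      responses[[nm]] <- response_params("stern_volmer", c(slope = f$slope),
                                         ch$response$reference_condition, rng)
      r2[nm] <- f$r_squared
    } else if (fam == "linear_ratio") {
      f <- fit_linear_ratio(cur$value - ch$response$reference_condition,
                            cur$ratio)
      responses[[nm]] <- response_params("linear_ratio", c(slope = f$slope),
                                         ch$response$reference_condition, rng)
      r2[nm] <- f$r_squared
    } else {
      f <- fit_logistic4(cur$value, cur$ratio,
                         midpoint_hint = ch$response$parameters[["c0"]])
      # renormalize so the reference condition maps to 1
      ref0 <- f$A + (f$B - f$A) * plogis(f$k * (ch$response$reference_condition - f$c0))
      responses[[nm]] <- response_params("logistic4",
        c(A = f$A / ref0, B = f$B / ref0, k = f$k, c0 = f$c0),
        ch$response$reference_condition, rng)
      r2[nm] <- f$r_squared
    }
    href <- cur$height[1L] / cur$ratio[1L]  # height at reference condition
    refint[nm] <- href
    laser_ref[[as.character(ch$excitation_nm)]] <-
      c(laser_ref[[as.character(ch$excitation_nm)]], href)
  }
  calibration_model(responses, r2, refint,
                    laser_references = lapply(laser_ref, mean),
                    source = "simulated characterization sweep")
}

#' Two-point session calibration against standard buffers
#'
#' Before each measurement session the instrument is calibrated with two
#' standard buffers of known composition. For every channel the measured
#' (photobleach-corrected) peak heights at the two standards, together
#' with the stored response curve, determine an affine correction
#' h = offset + gain * reference_intensity * R(c): the returned model
#' inverts measurements exactly at the two standards. An unperturbed
#' instrument yields gain 1 and offset 0.
#'
#' @param measured_features list of two `feature_vector`s (photobleach
#'   corrected) measured in the two standards.
#' @param expected_states list of two [biomarker_state()]s: the standards'
#'   compositions.
#' @param model the stored [calibration_model()].
#' @return the updated `calibration_model`.
#' @export
two_point_calibrate <- function(measured_features, expected_states, model) {
  stopifnot(length(measured_features) == 2L, length(expected_states) == 2L)
  s1 <- as_biomarker_state(expected_states[[1L]])
  s2 <- as_biomarker_state(expected_states[[2L]])
  for (fv in measured_features)
    if (!isTRUE(attr(fv, "corrected")))
      stop("two_point_calibrate: features must be photobleach-corrected",
           call. = FALSE)
  h <- lapply(measured_features, function(fv)
    setNames(fv$height, fv$channel))
  for (nm in names(model$responses)) {
    if (s1[[nm]] == s2[[nm]])
      stop("two_point_calibrate: the two standards do not differ in ", nm,
           call. = FALSE)
    r1 <- response_ratio(model$responses[[nm]], s1[[nm]])
    r2 <- response_ratio(model$responses[[nm]], s2[[nm]])
    K <- (h[[2L]][[nm]] - h[[1L]][[nm]]) / (r2 - r1)
    o <- h[[1L]][[nm]] - K * r1
    model$two_point_gains[[nm]] <- list(gain = K / model$reference_intensity[[nm]],
                                        offset = o)
  }
  # refresh per-laser standardization references to the session's scale
  assign <- laser_assignment()
  model$laser_references <- lapply(assign, function(chs)
    mean(vapply(chs, function(nm)
      model$two_point_gains[[nm]]$gain * model$reference_intensity[[nm]],
      numeric(1))))
  model
}

#' Classical (curve-inversion) concentration readout
#'
#' Inverts each channel's fitted, gain-corrected response curve at the
#' measured peak height: the non-ML readout path. With overlapping
#' emission peaks this path is only exact when one analyte varies at a
#' time; the regression layer exists to lift that restriction.
#'
#' @param model a [calibration_model()] (after [two_point_calibrate()] for
#'   session accuracy).
#' @param features a photobleach-corrected `feature_vector`.
#' @param clip clamp ratios to each curve's attainable range before
#'   inversion.
#' @return a [biomarker_state()] estimate.
#' @export
predict_classical <- function(model, features, clip = TRUE) {
  if (!isTRUE(attr(features, "corrected")))
    stop("predict_classical: features must be photobleach-corrected", call. = FALSE)
  h <- setNames(features$height, features$channel)
  est <- lapply(setNames(names(model$responses), names(model$responses)),
                function(nm) {
    g <- model$two_point_gains[[nm]]
    ratio <- (h[[nm]] - g$offset) / (g$gain * model$reference_intensity[[nm]])
    pars <- model$responses[[nm]]
    if (clip) {
      att <- sort(response_ratio(pars, pars$valid_range))
      ratio <- min(max(ratio, att[1]), att[2])
    }
    invert_ratio(pars, ratio)
  })
  as_biomarker_state(unlist(est), clip = TRUE)
}

#' Default two-point calibration standard buffers
#'
#' Compositions of the low and high standard buffers used for the
#' two-point session calibration: every channel's analyte differs between
#' the two.
#'
#' @return list with `low` and `high` [biomarker_state()]s.
#' @export
default_standards <- function() {
  list(low  = biomarker_state(34, 2, 6.5, 40, 0.4, 1),
       high = biomarker_state(40, 7, 7.8, 160, 1.6, 5))
}
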