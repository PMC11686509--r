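#' Calibration response-curve parameters for one sensor channel
#'
#' Three curve families describe how a channel's emitted intensity depends
#' on its analyte, always expressed as the emission ratio I/I0 relative to
#' the reference condition (where the ratio is exactly 1):
#'
#' * `linear_ratio`: I/I0 = 1 + slope * (x - reference). Used for the
#'   sodium channel (emission grows linearly with Na+).
#' * `stern_volmer`: collisional quenching, I0/I = 1 + slope * (x - reference),
#'   so I/I0 = 1 / (1 + slope * (x - reference)). Used for temperature and
#'   dissolved oxygen, whose emission is quenched by the analyte.
#' * `logistic4`: four-parameter logistic in I/I0,
#'   R(x) = A + (B - A) / (1 + exp(-k (x - c0))). Used for pH, glucose and
#'   calcium (indicator-binding sigmoids).
#'
#' @param family one of `"linear_ratio"`, `"stern_volmer"`, `"logistic4"`.
#' @param parameters named numeric vector: `slope` for the linear families;
#'   `A`, `B`, `k`, `c0` for `logistic4`.
#' @param reference_condition analyte value at which I/I0 is defined as 1.
#' @param valid_range `c(lo, hi)` analyte range the curve is valid over.
#' @return object of class `response_params`.
#' @export
response_params <- function(family, parameters, reference_condition, valid_range) {
  family <- match.arg(family, c("linear_ratio", "stern_volmer", "logistic4"))
  need <- if (family == "logistic4") c("A", "B", "k", "c0") else "slope"
  if (!all(need %in% names(parameters)))
    stop("response_params: family '", family, "' needs parameters ",
         paste(need, collapse = ", "), call. = FALSE)
  obj <- structure(list(family = family,
                        parameters = parameters,
                        reference_condition = reference_condition,
                        valid_range = as.numeric(valid_range)),
                   class = "response_params")
  r0 <- response_ratio(obj, reference_condition)
  if (abs(r0 - 1) > 1e-9)
    stop(sprintf("response_params: ratio at reference condition is %.6g, not 1 (mis-normalized parameters)", r0),
         call. = FALSE)
  obj
}

#' Evaluate a response curve at given analyte values
#'
#' Returns the emission ratio I/I0 (dimensionless). For the quenched
#' families the underlying Stern-Volmer line lives in I0/I; this function
#' always returns the emitted-intensity ratio I/I0, i.e. the factor the
#' peak amplitude is multiplied by.
#'
#' @param params a [response_params()] object.
#' @param x analyte values (vectorized).
#' @return numeric vector of I/I0 ratios.
#' @export
response_ratio <- function(params, x) {
  p <- params$parameters
  switch(params$family,
    linear_ratio = 1 + p[["slope"]] * (x - params$reference_condition),
    stern_volmer = 1 / (1 + p[["slope"]] * (x - params$reference_condition)),
    logistic4    = {
      r <- p[["A"]] + (p[["B"]] - p[["A"]]) * plogis(p[["k"]] * (x - p[["c0"]]))
      # renormalize so reference maps to exactly 1
      r0 <- p[["A"]] + (p[["B"]] - p[["A"]]) *
        plogis(p[["k"]] * (params$reference_condition - p[["c0"]]))
      r / r0
    },
    stop("unknown response family: ", params$family, call. = FALSE))
}

#' Invert a response curve: emission ratio to concentration
#'
#' Closed-form inverse of [response_ratio()]. Linear families invert
#' algebraically; the four-parameter logistic inverts through the logit.
#'
#' @param params a [response_params()] object.
#' @param ratio I/I0 emission ratios (vectorized).
#' @return analyte values.
#' @export
invert_ratio <- function(params, ratio) {
  p <- params$parameters
  rng <- params$valid_range
  att <- sort(response_ratio(params, rng))
  tol <- 1e-9 * max(1, abs(att))
  if (any(ratio < att[1] - tol | ratio > att[2] + tol))
    stop(sprintf("invert_ratio: ratio outside attainable range [%.6g, %.6g]; nearest attainable bound is %.6g",
                 att[1], att[2],
                 ifelse(ratio[which.max(abs(ratio - mean(att)))] < att[1], att[1], att[2])),
         call. = FALSE)
  switch(params$family,
    linear_ratio = params$reference_condition + (ratio - 1) / p[["slope"]],
    stern_volmer = params$reference_condition + (1 / ratio - 1) / p[["slope"]],
    logistic4    = {
      r0 <- p[["A"]] + (p[["B"]] - p[["A"]]) *
        plogis(p[["k"]] * (params$reference_condition - p[["c0"]]))
      f <- (ratio * r0 - p[["A"]]) / (p[["B"]] - p[["A"]])
      f <- pmin(pmax(f, 1e-15), 1 - 1e-15)
      p[["c0"]] + qlogis(f) / p[["k"]]
    })
}

#' Slope of a response curve at its logistic midpoint
#'
#' For `logistic4` curves this is the maximum slope (B - A) k / 4 on the
#' normalized I/I0 scale; for linear families it is the constant slope.
#'
#' @param params a [response_params()] object.
#' @return slope in ratio units per analyte unit.
#' @export
midpoint_slope <- function(params) {
  p <- params$parameters
  switch(params$family,
    linear_ratio = p[["slope"]],
    stern_volmer = -p[["slope"]],
    logistic4    = {
      r0 <- p[["A"]] + (p[["B"]] - p[["A"]]) *
        plogis(p[["k"]] * (params$reference_condition - p[["c0"]]))
      (p[["B"]] - p[["A"]]) * p[["k"]] / 4 / r0
    })
}

# ---- default per-channel response curves ------------------------------------
#
# Constants are solved in closed form from the printed calibration facts:
#   temperature: I0/I = 1 + 0.04 (T - 33), reference 33 degC
#   DO:          I0/I = 1 + 0.38 [DO],     reference 0 mg/L
#   pH:          logistic4 in I/I0, midpoint 7.0; steepness and amplitudes
#                solved so the midpoint slope is 2.624 per pH unit and
#                R(8)/R(6) = 5 with R(6) = 1
#   Na+:         I/I0 = 1 + 0.0064 [Na+],  reference 0 mmol/L
#   Ca2+:        logistic4, midpoint 0.5 mmol/L (indicator Kd), k = 2;
#                amplitude solved so the straight-line slope over the
#                physiological window grid (1.0, 1.1, 1.2, 1.3 mmol/L)
#                is 0.41 per mmol/L, with R(0) = 1
#   glucose:     logistic4, midpoint 3 mmol/L, k = 1; amplitudes solved so
#                R(5)/R(1) = 4 with R(0) = 1

solve_ph_response <- function(sens = 2.624, fold = 5, lo = 6, hi = 8, c0 = 7) {
  # find k with D = 4*sens/k and D*tanh(k/2) = fold - 1 (R(lo)=1, R(hi)=fold)
  g <- function(k) (4 * sens / k) * tanh(k * (hi - lo) / 4) - (fold - 1)
  k <- uniroot(g, c(1e-3, 50), tol = 1e-12)$root
  D <- 4 * sens / k
  u <- plogis(k * (lo - c0))
  A <- 1 - D * u
  response_params("logistic4", c(A = A, B = A + D, k = k, c0 = c0),
                  reference_condition = lo, valid_range = c(lo, hi))
}

solve_glucose_response <- function(fold = 4, at = c(1, 5), k = 1, c0 = 3) {
  f <- function(c) plogis(k * (c - c0))
  # R(0) = 1 and R(at2) = fold * R(at1)
  D <- 1 / ((f(at[2]) - fold * f(at[1])) / (fold - 1) + f(0))
  A <- D * (f(at[2]) - fold * f(at[1])) / (fold - 1)
  response_params("logistic4", c(A = A, B = A + D, k = k, c0 = c0),
                  reference_condition = 0, valid_range = c(0, 6))
}

solve_calcium_response <- function(sens = 0.41, window = c(1.0, 1.35),
                                   k = 2, c0 = 0.5) {
  cw <- seq(window[1], window[2], by = 0.1)
  cw <- cw[cw <= window[2]]
  fw <- plogis(k * (cw - c0))
  D <- sens / (cov(cw, fw) / var(cw))
  A <- 1 - D * plogis(k * (0 - c0))
  response_params("logistic4", c(A = A, B = A + D, k = k, c0 = c0),
                  reference_condition = 0, valid_range = c(0, 3))
}

default_response <- function(name) {
  switch(name,
    temperature = response_params("stern_volmer", c(slope = 0.04),
                                  reference_condition = 33, valid_range = c(33, 42)),
    dissolved_oxygen = response_params("stern_volmer", c(slope = 0.38),
                                       reference_condition = 0, valid_range = c(0, 8)),
    pH       = solve_ph_response(),
    sodium   = response_params("linear_ratio", c(slope = 0.0064),
                               reference_condition = 0, valid_range = c(0, 200)),
    calcium  = solve_calcium_response(),
    glucose  = solve_glucose_response(),
    stop("unknown channel name: ", name, call. = FALSE))
}
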