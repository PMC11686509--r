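#' The six CSF biomarker levels handled by the system
#'
#' A `biomarker_state` holds one value per monitored quantity, in the units
#' the sensors are calibrated in: temperature (deg C), dissolved oxygen
#' (mg/L), pH (pH units), sodium (mmol/L), calcium (mmol/L), glucose
#' (mmol/L).
#'
#' Admissible ranges are those the sensors were characterized over:
#' temperature 33-42 deg C, dissolved oxygen 0-8 mg/L, pH 6-8, sodium
#' 0-200 mmol/L, calcium 0-3 mmol/L, glucose 0-6 mmol/L. Values outside an
#' admissible range raise an error unless `clip = TRUE`, in which case they
#' are clamped to the range boundary.
#'
#' @param temperature temperature in deg C.
#' @param dissolved_oxygen dissolved oxygen in mg/L.
#' @param pH pH.
#' @param sodium sodium concentration in mmol/L.
#' @param calcium calcium concentration in mmol/L.
#' @param glucose glucose concentration in mmol/L.
#' @param clip clamp out-of-range values to the admissible range instead of
#'   raising an error.
#' @return a named numeric vector of class `biomarker_state`.
#' @examples
#' healthy_state()
#' biomarker_state(temperature = 38, dissolved_oxygen = 3.2)
#' @export
biomarker_state <- function(temperature = 37,
                            dissolved_oxygen = 6.5,
                            pH = 7.35,
                            sodium = 145,
                            calcium = 1.2,
                            glucose = 3.3,
                            clip = FALSE) {
  x <- c(temperature = temperature, dissolved_oxygen = dissolved_oxygen,
         pH = pH, sodium = sodium, calcium = calcium, glucose = glucose)
  if (any(!is.finite(x)))
    stop("biomarker_state: all six values must be finite", call. = FALSE)
  rng <- biomarker_ranges()
  for (nm in names(x)) {
    lo <- rng[[nm]][1L]; hi <- rng[[nm]][2L]
    if (x[[nm]] < lo || x[[nm]] > hi) {
      if (clip) {
        x[[nm]] <- min(max(x[[nm]], lo), hi)
      } else {
        stop(sprintf("biomarker_state: %s = %g outside admissible range [%g, %g] (use clip = TRUE to clamp)",
                     nm, x[[nm]], lo, hi), call. = FALSE)
      }
    }
  }
  structure(x, class = "biomarker_state")
}

#' Admissible simulator ranges for the six biomarkers
#'
#' @return named list of `c(lo, hi)` per biomarker.
#' @export
biomarker_ranges <- function() {
  list(temperature      = c(33, 42),
       dissolved_oxygen = c(0, 8),
       pH               = c(6, 8),
       sodium           = c(0, 200),
       calcium          = c(0, 3),
       glucose          = c(0, 6))
}

#' @export
print.biomarker_state <- function(x, ...) {
  units <- c(temperature = "degC", dissolved_oxygen = "mg/L", pH = "",
             sodium = "mmol/L", calcium = "mmol/L", glucose = "mmol/L")
  cat("<biomarker_state>\n")
  for (nm in names(unclass(x)))
    cat(sprintf("  %-17s %8.3f %s\n", nm, x[[nm]], units[[nm]]))
  invisible(x)
}

#' Names of the six biomarkers, in canonical order
#' @return character vector.
#' @export
biomarker_names <- function() {
  c("temperature", "dissolved_oxygen", "pH", "sodium", "calcium", "glucose")
}

#' Healthy resting CSF state
#'
#' Nominal healthy values used as the default scenario baseline:
#' 37 deg C, 6.5 mg/L dissolved oxygen, pH 7.35, 145 mmol/L Na+,
#' 1.2 mmol/L Ca2+, 3.3 mmol/L glucose.
#'
#' @return a [biomarker_state()].
#' @export
healthy_state <- function() biomarker_state()

as_biomarker_state <- function(x, clip = FALSE) {
  if (inherits(x, "biomarker_state")) return(x)
  x <- unlist(x)
  if (is.null(names(x)) && length(x) == 6L) names(x) <- biomarker_names()
  miss <- setdiff(biomarker_names(), names(x))
  if (length(miss))
    stop("missing biomarker values: ", paste(miss, collapse = ", "), call. = FALSE)
  do.call(biomarker_state, c(as.list(x[biomarker_names()]), list(clip = clip)))
}
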