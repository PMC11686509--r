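#' Savitzky-Golay denoising of a spectral frame
#'
#' Moving-window polynomial smoothing. Window length must be odd and the
#' polynomial order smaller than the window; a polynomial signal of degree
#' <= `order` passes through unchanged (interior pixels).
#'
#' @param frame a [spectral_frame()] or numeric vector.
#' @param window odd window length in pixels, 3..101.
#' @param order polynomial order, < `window`.
#' @return same type as `frame`, smoothed.
#' @export
denoise <- function(frame, window = 11, order = 3) {
  if (window %% 2 == 0)
    stop("denoise: window must be odd", call. = FALSE)
  if (window < 3 || window > 101)
    stop("denoise: window must be in [3, 101]", call. = FALSE)
  if (order >= window)
    stop("denoise: order must be < window", call. = FALSE)
  y <- if (inherits(frame, "spectral_frame")) frame$intensities else frame
  z <- signal::sgolayfilt(y, p = order, n = window)
  if (inherits(frame, "spectral_frame")) {
    frame$intensities <- z
    frame$provenance <- union(frame$provenance, "denoise")
    frame
  } else z
}

.whittaker_cache <- new.env(parent = emptyenv())

whittaker_penalty <- function(m) {
  key <- as.character(m)
  P <- .whittaker_cache[[key]]
  if (is.null(P)) {
    D <- Matrix::diff(Matrix::Diagonal(m), differences = 2)
    P <- Matrix::crossprod(D)
    .whittaker_cache[[key]] <- P
  }
  P
}

whittaker_fit <- function(y, w, lambda) {
  m <- length(y)
  as.numeric(Matrix::solve(Matrix::Diagonal(m, w) + lambda * whittaker_penalty(m),
                           w * y))
}

als_baseline <- function(y, lambda, p, iterations) {
  w <- rep(1, length(y))
  z <- y
  converged <- FALSE
  for (i in seq_len(iterations)) {
    z <- whittaker_fit(y, w, lambda)
    wn <- ifelse(y > z, p, 1 - p)
    if (all(wn == w)) { converged <- TRUE; break }
    w <- wn
  }
  if (!converged)
    warning("baseline_correct: weights still changing after ", iterations,
            " iterations; returning last iterate", call. = FALSE)
  z
}

airpls_baseline <- function(y, lambda, iterations) {
  m <- length(y)
  w <- rep(1, m)
  ay <- sum(abs(y))
  z <- numeric(m)
  for (i in seq_len(iterations)) {
    z <- whittaker_fit(y, w, lambda)
    d <- y - z
    dn <- d[d < 0]
    if (!length(dn) || sum(abs(dn)) < 1e-3 * ay) break
    w <- ifelse(d >= 0, 0, exp(i * abs(d) / sum(abs(dn))))
    w[1] <- w[m] <- exp(i * max(abs(dn)) / sum(abs(dn)))
  }
  z
}

#' Penalized least-squares baseline correction
#'
#' Estimates and subtracts a smooth baseline by iteratively reweighted
#' Whittaker smoothing (second-difference penalty `smoothness`).
#'
#' The default `"adaptive"` method runs an adaptive-reweighting pass
#' (points above the current baseline are progressively excluded) and then
#' re-fits a stiff baseline restricted to the identified baseline support,
#' which keeps heavy Lorentzian peak tails out of the baseline estimate.
#' Method `"als"` is the classic fixed-asymmetry scheme: points above the
#' current baseline get weight `asymmetry`, points below `1 - asymmetry`.
#' Both methods are exactly scale-equivariant, so peak-height ratios are
#' preserved.
#'
#' @param frame a [spectral_frame()] or numeric vector.
#' @param smoothness second-difference penalty lambda (> 0).
#' @param asymmetry weight p for points above the baseline (0 < p < 1;
#'   `"als"` method only).
#' @param iterations maximum reweighting iterations.
#' @param method `"adaptive"` (default) or `"als"`.
#' @return same type as `frame`, baseline-subtracted.
#' @export
baseline_correct <- function(frame, smoothness = 1e5, asymmetry = 0.01,
                             iterations = 30, method = c("adaptive", "als")) {
  method <- match.arg(method)
  if (smoothness <= 0) stop("baseline_correct: smoothness must be > 0", call. = FALSE)
  if (asymmetry <= 0 || asymmetry >= 1)
    stop("baseline_correct: asymmetry must be in (0, 1)", call. = FALSE)
  y <- if (inherits(frame, "spectral_frame")) frame$intensities else frame
  if (max(abs(y)) == 0) {
    z <- y * 0
  } else if (method == "als") {
    z <- als_baseline(y, smoothness, asymmetry, iterations)
  } else {
    z <- airpls_baseline(y, smoothness, iterations)
    if (max(y - z) >= 0.02 * max(abs(y))) {
      # peaks present: re-fit a stiff baseline on the classified baseline
      # support so peak tails do not inflate the estimate
      for (j in 1:3) {
        d <- y - z
        neg <- d[d < 0]
        s <- if (length(neg)) sqrt(mean(neg^2)) else 0
        th <- max(0.006 * max(d), 3 * s)
        w <- ifelse(d < th, 1, 1e-8)
        z <- whittaker_fit(y, w, 100 * smoothness)
      }
    }
  }
  out <- y - z
  if (inherits(frame, "spectral_frame")) {
    frame$intensities <- out
    frame$provenance <- union(frame$provenance, "baseline_correct")
    frame
  } else out
}

#' Standardize a frame against a stored calibration reference
#'
#' Divides all intensities by the per-laser reference intensity recorded at
#' calibration time, making spectra comparable across sessions and laser
#' powers. Output is dimensionless.
#'
#' @param frame a [spectral_frame()].
#' @param reference positive reference intensity for the frame's laser, or
#'   a [calibration_model()] holding per-laser references.
#' @return the standardized frame.
#' @export
standardize <- function(frame, reference) {
  if (inherits(reference, "calibration_model"))
    reference <- reference$laser_references[[as.character(frame$excitation_nm)]]
  if (is.null(reference) || !is.finite(reference) || reference <= 0)
    stop("standardize: calibration required - no positive reference intensity for the ",
         frame$excitation_nm, " nm laser", call. = FALSE)
  frame$intensities <- frame$intensities / reference
  frame$provenance <- union(frame$provenance, "standardize")
  frame
}

#' Merge the three per-laser frames into one measurement vector
#'
#' Concatenates the 405, 488 and 520 nm frames, in that fixed order, into
#' the 1380-point merged spectrum; pixel j of the 488 nm frame maps to
#' merged index 460 + j, etc.
#'
#' @param frames list of exactly three [spectral_frame()]s, one per laser
#'   (any order).
#' @return object of class `merged_spectrum` with fields `intensities`
#'   (length 1380), `exposure_map`, `timestamp`, `label` (NULL until
#'   [set_label()]), `provenance`.
#' @export
merge_frames <- function(frames) {
  lasers <- vapply(frames, `[[`, numeric(1), "excitation_nm")
  if (length(frames) != 3L || anyDuplicated(lasers) ||
      !setequal(lasers, c(405, 488, 520)))
    stop("merge_frames: need exactly one frame per laser (405, 488, 520); got ",
         paste(lasers, collapse = ", "), call. = FALSE)
  ord <- match(c(405, 488, 520), lasers)
  frames <- frames[ord]
  structure(list(
    intensities = unlist(lapply(frames, `[[`, "intensities"), use.names = FALSE),
    exposure_map = setNames(vapply(frames, function(f)
      if (is.null(f$exposure_units)) f$cumulative_on_time else f$exposure_units,
      numeric(1)), c("405", "488", "520")),
    timestamp = max(vapply(frames, `[[`, numeric(1), "timestamp")),
    label = NULL,
    provenance = Reduce(union, lapply(frames, `[[`, "provenance"))),
    class = "merged_spectrum")
}

#' Split a merged spectrum back into its three per-laser frames
#'
#' Inverse of [merge_frames()] (up to per-frame timestamps, which all
#' carry the merged timestamp).
#'
#' @param merged a `merged_spectrum`.
#' @return named list of three [spectral_frame()]s.
#' @export
unmerge <- function(merged) {
  stopifnot(inherits(merged, "merged_spectrum"))
  out <- lapply(c("405", "488", "520"), function(l) {
    seg <- laser_segment(as.numeric(l))
    f <- spectral_frame(as.numeric(l),
                        merged$intensities[(seg[1] + 1L):(seg[2] + 1L)],
                        cumulative_on_time = merged$exposure_map[[l]],
                        timestamp = merged$timestamp)
    f$provenance <- merged$provenance
    f
  })
  setNames(out, c("405", "488", "520"))
}

#' Attach the six-biomarker label to a merged spectrum
#'
#' Idempotent overwrite: relabeling replaces any existing label.
#'
#' @param merged a `merged_spectrum`.
#' @param state a [biomarker_state()].
#' @return the labeled spectrum.
#' @export
set_label <- function(merged, state) {
  stopifnot(inherits(merged, "merged_spectrum"))
  merged$label <- as_biomarker_state(state)
  merged
}

#' @export
print.merged_spectrum <- function(x, ...) {
  cat(sprintf("<merged_spectrum> %d px  max %.4g  %s  steps: %s\n",
              length(x$intensities), max(x$intensities),
              if (is.null(x$label)) "unlabeled" else "labeled",
              if (length(x$provenance)) paste(x$provenance, collapse = " > ") else "raw"))
  invisible(x)
}

#' Preprocess and merge one scan's raw frames
#'
#' Applies the fixed pipeline order - denoise, baseline-correct, optionally
#' standardize - to each of the three frames, then merges and (when a true
#' state is supplied) labels the result.
#'
#' @param frames named list of three raw [spectral_frame()]s.
#' @param state optional true [biomarker_state()] label.
#' @param window,order [denoise()] parameters.
#' @param smoothness,asymmetry,method [baseline_correct()] parameters.
#' @param calibration optional [calibration_model()]; when given, frames
#'   are standardized against its per-laser references.
#' @return a `merged_spectrum`.
#' @export
preprocess_scan <- function(frames, state = NULL, window = 11, order = 3,
                            smoothness = 1e5, asymmetry = 0.01,
                            method = "adaptive", calibration = NULL) {
  frames <- lapply(frames, function(f) {
    f <- denoise(f, window = window, order = order)
    f <- baseline_correct(f, smoothness = smoothness, asymmetry = asymmetry,
                          method = method)
    if (!is.null(calibration)) f <- standardize(f, calibration)
    f
  })
  m <- merge_frames(frames)
  if (!is.null(state)) m <- set_label(m, state)
  m
}
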