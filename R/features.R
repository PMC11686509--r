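#' Extract per-channel peak features from a merged spectrum
#'
#' For every channel, five features are computed from its segment of the
#' (baseline-corrected) merged spectrum:
#'
#' * `height` - intensity at the channel's fixed nominal peak index (the
#'   six instrument wavelengths; clipped at zero if negative).
#' * `position` - merged index of the located local maximum within
#'   `search_radius` pixels of the nominal index (peaks shift slightly
#'   with concentration); falls back to the nominal index when no local
#'   maximum exists in the window.
#' * `prominence` - located peak intensity minus the higher of the two
#'   flanking local minima.
#' * `width` - full width at half prominence, pixels (linear
#'   interpolation at the half-prominence crossings).
#' * `area` - trapezoidal integral between the nearest flanking local
#'   minima.
#'
#' @param merged a `merged_spectrum` (should be baseline-corrected).
#' @param channels channel set, default [default_channels()].
#' @param search_radius half-width of the peak search window, pixels.
#' @return object of class `feature_vector`: a data.frame (one row per
#'   channel) with attributes `exposure` (per-channel exposure used),
#'   `corrected` (FALSE), and `label` (the spectrum's label, if any).
#' @export
extract_features <- function(merged, channels = default_channels(),
                             search_radius = 15) {
  stopifnot(inherits(merged, "merged_spectrum"))
  v <- merged$intensities
  if (length(v) != 3L * segment_length())
    stop("extract_features: merged spectrum must have length ",
         3L * segment_length(), call. = FALSE)
  rows <- lapply(channels, function(ch) {
    seg <- laser_segment(ch$excitation_nm)
    nominal <- ch$merged_peak_index
    lo <- max(seg[1], nominal - search_radius)
    hi <- min(seg[2], nominal + search_radius)
    win <- (lo:hi) + 1L                      # 1-based
    # local maxima strictly inside the segment
    is_max <- vapply(win, function(i) {
      i > seg[1] + 1L && i < seg[2] + 1L &&
        v[i] >= v[i - 1L] && v[i] >= v[i + 1L] &&
        (v[i] > v[i - 1L] || v[i] > v[i + 1L])
    }, logical(1))
    pos1 <- if (any(is_max)) win[is_max][which.max(v[win[is_max]])] else nominal + 1L
    peakval <- v[pos1]
    # flanking local minima (or segment boundary)
    l <- pos1
    while (l > seg[1] + 1L && v[l - 1L] <= v[l]) l <- l - 1L
    r <- pos1
    while (r < seg[2] + 1L && v[r + 1L] <= v[r]) r <- r + 1L
    prom <- peakval - max(v[l], v[r])
    area <- if (r > l) sum((v[(l + 1L):r] + v[l:(r - 1L)]) / 2) else 0
    # full width at half prominence
    half <- peakval - prom / 2
    xl <- pos1
    while (xl > l && v[xl - 1L] >= half) xl <- xl - 1L
    left <- if (xl > l && v[xl - 1L] < v[xl])
      (xl - 1L) + (half - v[xl - 1L]) / (v[xl] - v[xl - 1L]) else as.numeric(l)
    xr <- pos1
    while (xr < r && v[xr + 1L] >= half) xr <- xr + 1L
    right <- if (xr < r && v[xr + 1L] < v[xr])
      xr + (v[xr] - half) / (v[xr] - v[xr + 1L]) else as.numeric(r)
    width <- right - left
    height <- v[nominal + 1L]
    clipped <- height < 0 || area < 0 || prom < 0
    data.frame(channel = ch$name,
               height = max(height, 0), width = width, area = max(area, 0),
               position = pos1 - 1L, prominence = max(prom, 0),
               clipped = clipped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  expo <- vapply(channels, function(ch)
    merged$exposure_map[[as.character(ch$excitation_nm)]], numeric(1))
  structure(out, class = c("feature_vector", "data.frame"),
            exposure = setNames(expo, out$channel),
            corrected = FALSE, label = merged$label)
}

#' Compensate peak features for photobleaching
#'
#' The emitted intensity decays as I(t) = I(0) exp(-t / tau) under
#' accumulated excitation, so the intensity-like features (height, area,
#' prominence) are rescaled by exp(t / tau) to their fresh-film (t = 0)
#' values. Peak width and position are left untouched: a Lorentzian peak
#' keeps its shape while bleaching. Re-correcting an already corrected
#' vector is an error.
#'
#' @param features a `feature_vector` from [extract_features()], or a wide
#'   feature table from [build_feature_table()].
#' @param taus named per-channel photobleaching constants.
#' @return the corrected object, with the `corrected` attribute set.
#' @export
photobleach_correct <- function(features, taus = default_taus()) {
  UseMethod("photobleach_correct")
}

check_taus <- function(taus, needed) {
  miss <- setdiff(needed, names(taus))
  if (length(miss))
    stop("photobleach_correct: missing tau for ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(taus[needed] <= 0))
    stop("photobleach_correct: tau must be positive", call. = FALSE)
}

#' @export
photobleach_correct.feature_vector <- function(features, taus = default_taus()) {
  if (isTRUE(attr(features, "corrected")))
    stop("photobleach_correct: features already corrected", call. = FALSE)
  check_taus(taus, features$channel)
  expo <- attr(features, "exposure")
  fac <- exp(expo[features$channel] / taus[features$channel])
  for (col in c("height", "area", "prominence"))
    features[[col]] <- features[[col]] * fac
  attr(features, "corrected") <- TRUE
  features
}

#' @export
photobleach_correct.data.frame <- function(features, taus = default_taus()) {
  if (isTRUE(attr(features, "corrected")))
    stop("photobleach_correct: features already corrected", call. = FALSE)
  chs <- unique(sub("_(height|width|area|position|prominence)$", "",
                    grep("_height$", names(features), value = TRUE)))
  check_taus(taus, chs)
  assign <- laser_assignment()
  for (ch in chs) {
    laser <- names(assign)[vapply(assign, function(x) ch %in% x, logical(1))]
    expo <- features[[paste0("exposure_", laser)]]
    if (is.null(expo))
      stop("photobleach_correct: no exposure_", laser, " column", call. = FALSE)
    fac <- exp(expo / taus[[ch]])
    for (f in c("height", "area", "prominence")) {
      col <- paste0(ch, "_", f)
      if (!is.null(features[[col]])) features[[col]] <- features[[col]] * fac
    }
  }
  attr(features, "corrected") <- TRUE
  features
}

#' Fit a photobleaching time constant from a decay trace
#'
#' Least-squares fit of I(t) = I0 exp(-t / tau): a linear regression on
#' log intensities provides the starting point, refined by nonlinear least
#' squares on the original scale.
#'
#' @param times exposure times (>= 3 distinct values).
#' @param intensities positive peak intensities.
#' @return list with `tau`, `I0` and `r_squared` (of the nonlinear fit).
#' @examples
#' t <- seq(0, 180, 10)
#' fit_tau(t, 3 * exp(-t / 48.8))$tau
#' @export
fit_tau <- function(times, intensities) {
  if (length(times) != length(intensities) || length(times) < 3)
    stop("fit_tau: need >= 3 (time, intensity) points", call. = FALSE)
  if (any(intensities <= 0))
    stop("fit_tau: intensities must be positive", call. = FALSE)
  if (sd(intensities) == 0 || sd(times) == 0)
    stop("fit_tau: degenerate (constant) series, cannot fit a decay", call. = FALSE)
  lf <- lsfit(times, log(intensities))
  slope <- lf$coefficients[2L]
  if (slope >= 0)
    stop("fit_tau: intensities do not decay with exposure", call. = FALSE)
  start <- list(I0 = exp(unname(lf$coefficients[1L])), tau = -1 / unname(slope))
  df <- data.frame(t = times, y = intensities)
  fit <- minpack.lm::nlsLM(y ~ I0 * exp(-t / tau), data = df, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  pred <- predict(fit)
  ss_res <- sum((intensities - pred)^2)
  ss_tot <- sum((intensities - mean(intensities))^2)
  list(tau = unname(coef(fit)[["tau"]]), I0 = unname(coef(fit)[["I0"]]),
       r_squared = 1 - ss_res / ss_tot)
}

#' Pearson-correlation feature selection
#'
#' Computes the Pearson correlation between every feature column and every
#' label column; a feature is selected when its largest absolute
#' correlation over the labels reaches `threshold`. Zero-variance features
#' get r = 0 (with a warning) and are never selected.
#'
#' @param feature_matrix numeric matrix or data.frame of features
#'   (columns) by samples (rows).
#' @param labels numeric matrix or data.frame of label columns.
#' @param threshold minimum max-|r| for selection.
#' @return object of class `feature_selection`: list with `mask` (named
#'   logical), `correlations` (features x labels matrix) and `threshold`.
#' @export
pearson_select <- function(feature_matrix, labels, threshold = 0.5) {
  X <- as.matrix(feature_matrix)
  Y <- as.matrix(labels)
  if (nrow(X) != nrow(Y) || nrow(X) < 3)
    stop("pearson_select: need >= 3 samples with matching rows", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("pearson_select: features and labels must be finite", call. = FALSE)
  const <- apply(X, 2, sd) == 0
  if (any(const))
    warning("pearson_select: zero-variance feature(s) get r = 0: ",
            paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  R <- matrix(0, ncol(X), ncol(Y), dimnames = list(colnames(X), colnames(Y)))
  if (any(!const))
    R[!const, ] <- suppressWarnings(cor(X[, !const, drop = FALSE], Y))
  R[is.na(R)] <- 0
  mask <- apply(abs(R), 1, max) >= threshold
  structure(list(mask = mask, correlations = R, threshold = threshold),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d / %d features selected at max |r| >= %g\n",
              sum(x$mask), length(x$mask), x$threshold))
  invisible(x)
}

#' Run the preprocessing + feature pipeline over a scan set
#'
#' Applies [preprocess_scan()] and [extract_features()] to every scan and
#' assembles the wide feature table used by the regression layer: columns
#' `{channel}_{height|width|area|position|prominence}`,
#' `exposure_{405|488|520}`, label columns `label_{biomarker}` and, for
#' scenario runs, `stage` and `time_s`.
#'
#' @param scans a `scan_set` from [generate_calibration_set()] or
#'   [generate_scenario()].
#' @param channels channel set (defaults to the set stored in `scans`).
#' @param search_radius peak search radius, pixels.
#' @param correct apply [photobleach_correct()] with `taus`.
#' @param taus per-channel photobleaching constants.
#' @param calibration optional [calibration_model()] for standardization.
#' @param ... further arguments to [preprocess_scan()].
#' @return data.frame, one row per scan, with attribute `corrected`.
#' @export
build_feature_table <- function(scans, channels = NULL, search_radius = 15,
                                correct = TRUE, taus = default_taus(),
                                calibration = NULL, ...) {
  stopifnot(inherits(scans, "scan_set"))
  if (is.null(channels)) channels <- scans$channels
  feat_names <- c("height", "width", "area", "position", "prominence")
  rows <- lapply(scans$scans, function(sc) {
    m <- preprocess_scan(sc$frames, state = sc$state,
                         calibration = calibration, ...)
    fv <- extract_features(m, channels, search_radius = search_radius)
    vals <- unlist(lapply(seq_len(nrow(fv)), function(i)
      setNames(as.numeric(fv[i, feat_names]),
               paste0(fv$channel[i], "_", feat_names))))
    expo <- m$exposure_map
    row <- c(vals, setNames(expo, paste0("exposure_", names(expo))))
    if (!is.null(sc$state))
      row <- c(row, setNames(as.numeric(sc$state),
                             paste0("label_", biomarker_names())))
    out <- as.data.frame(as.list(row))
    if (!is.null(sc$stage)) { out$stage <- sc$stage; out$time_s <- sc$time_s }
    out
  })
  tab <- do.call(rbind, rows)
  attr(tab, "corrected") <- FALSE
  if (correct) tab <- photobleach_correct(tab, taus)
  tab
}

#' Column helpers for feature tables
#'
#' `feature_cols()` returns the feature column names of a wide feature
#' table (optionally restricted to given feature kinds); `label_cols()`
#' the label columns.
#'
#' @param tab a feature table from [build_feature_table()].
#' @param kinds feature kinds to keep, subset of
#'   `c("height", "width", "area", "position", "prominence")`.
#' @return character vector of column names.
#' @export
feature_cols <- function(tab, kinds = c("height", "width", "area",
                                        "position", "prominence")) {
  pat <- paste0("_(", paste(kinds, collapse = "|"), ")$")
  grep(pat, names(tab), value = TRUE)
}

#' @rdname feature_cols
#' @export
label_cols <- function(tab) grep("^label_", names(tab), value = TRUE)
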