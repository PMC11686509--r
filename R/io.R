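#' Read and write spectra in the package's CSV dialect
#'
#' Two on-disk forms are supported. A single frame is a two-column CSV
#' with header `pixel,intensity` plus a JSON sidecar (`<path>.json`) with
#' `excitation_nm`, `cumulative_on_time_s`, `timestamp_s` and optionally
#' `label`. A collection of merged spectra is a wide CSV with columns
#' `m0..m1379`, `exposure_405/488/520`, `timestamp` and, when labels are
#' present, `label_{biomarker}` columns. Intensities are written as
#' decimal text with 12 significant digits, so a write/read round trip is
#' lossless to working precision.
#'
#' @param x a [spectral_frame()], a `merged_spectrum`, or a list of merged
#'   spectra.
#' @param path file path.
#' @return `write_spectra()` returns `path` invisibly; `read_spectra()`
#'   returns a list of `merged_spectrum` (wide form) and `read_frame()` a
#'   `spectral_frame`.
#' @export
write_spectra <- function(x, path) {
  if (inherits(x, "spectral_frame")) return(write_frame(x, path))
  if (inherits(x, "merged_spectrum")) x <- list(x)
  rows <- lapply(x, function(m) {
    stopifnot(inherits(m, "merged_spectrum"))
    row <- c(setNames(m$intensities, paste0("m", seq_along(m$intensities) - 1L)),
             setNames(m$exposure_map, paste0("exposure_", names(m$exposure_map))),
             timestamp = m$timestamp)
    if (!is.null(m$label))
      row <- c(row, setNames(as.numeric(m$label),
                             paste0("label_", biomarker_names())))
    row
  })
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L)
    stop("write_spectra: spectra disagree on labeling; write separately",
         call. = FALSE)
  tab <- do.call(rbind, rows)
  out <- as.data.frame(apply(tab, 2, function(col) formatC(col, digits = 12,
                                                           format = "g")),
                       stringsAsFactors = FALSE)
  if (nrow(tab) == 1L) { out <- as.data.frame(t(out)); names(out) <- colnames(tab) }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  mcols <- grep("^m[0-9]+$", names(tab), value = TRUE)
  want <- paste0("m", seq_len(3L * segment_length()) - 1L)
  if (!identical(sort(as.integer(sub("^m", "", mcols))),
                 seq_len(3L * segment_length()) - 1L))
    stop("read_spectra: format error - expected columns m0..m1379, found ",
         length(mcols), " intensity columns in ", path, call. = FALSE)
  has_label <- all(paste0("label_", biomarker_names()) %in% names(tab))
  lapply(seq_len(nrow(tab)), function(i) {
    v <- as.numeric(tab[i, want])
    if (any(!is.finite(v)))
      stop("read_spectra: format error - non-numeric intensity in row ", i,
           call. = FALSE)
    m <- structure(list(
      intensities = v,
      exposure_map = c("405" = tab$exposure_405[i], "488" = tab$exposure_488[i],
                       "520" = tab$exposure_520[i]),
      timestamp = tab$timestamp[i],
      label = NULL, provenance = character(0)), class = "merged_spectrum")
    if (has_label)
      m$label <- as_biomarker_state(setNames(
        as.numeric(tab[i, paste0("label_", biomarker_names())]),
        biomarker_names()), clip = TRUE)
    m
  })
}

write_frame <- function(frame, path) {
  df <- data.frame(pixel = seq_along(frame$intensities) - 1L,
                   intensity = formatC(frame$intensities, digits = 12,
                                       format = "g"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(excitation_nm = frame$excitation_nm,
               cumulative_on_time_s = frame$cumulative_on_time,
               timestamp_s = frame$timestamp)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_frame <- function(path) {
  df <- read.csv(path)
  if (!identical(names(df), c("pixel", "intensity")))
    stop("read_frame: format error - expected header pixel,intensity",
         call. = FALSE)
  if (nrow(df) != segment_length())
    stop("read_frame: format error - expected ", segment_length(),
         " rows, found ", nrow(df), call. = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spectral_frame(side$excitation_nm, df$intensity,
                 cumulative_on_time = side$cumulative_on_time_s,
                 timestamp = side$timestamp_s)
}

#' Persist feature tables
#'
#' CSV plus a small JSON sidecar carrying the photobleach-correction
#' state, so the predict-time guard survives the round trip.
#'
#' @param tab feature table from [build_feature_table()].
#' @param path CSV path.
#' @export
write_feature_table <- function(tab, path) {
  out <- as.data.frame(lapply(tab, function(col)
    if (is.numeric(col)) formatC(col, digits = 12, format = "g") else col),
    check.names = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(corrected = isTRUE(attr(tab, "corrected"))),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".json")
  corrected <- if (file.exists(meta_path))
    isTRUE(jsonlite::read_json(meta_path)$corrected) else FALSE
  attr(tab, "corrected") <- corrected
  tab
}

# ---- model persistence ------------------------------------------------------

response_to_list <- function(rp) {
  list(family = rp$family, parameters = as.list(rp$parameters),
       reference_condition = rp$reference_condition,
       valid_range = rp$valid_range)
}

response_from_list <- function(l) {
  response_params(l$family, unlist(l$parameters), l$reference_condition,
                  unlist(l$valid_range))
}

#' Save / load a calibration model as versioned JSON
#'
#' @param model a [calibration_model()].
#' @param path JSON file path.
#' @return `load_calibration()` returns the restored model; the round trip
#'   is lossless.
#' @export
save_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- list(schema = "fiberspec/calibration/v1",
              responses = lapply(model$responses, response_to_list),
              fit_r2 = as.list(model$fit_r2),
              reference_intensity = as.list(model$reference_intensity),
              two_point_gains = model$two_point_gains,
              laser_references = model$laser_references,
              taus = as.list(model$taus),
              created_at = model$created_at, source = model$source)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "fiberspec/calibration/v1"))
    stop("load_calibration: unknown schema: ", obj$schema, call. = FALSE)
  m <- calibration_model(
    responses = lapply(obj$responses, response_from_list),
    fit_r2 = unlist(obj$fit_r2),
    reference_intensity = unlist(obj$reference_intensity),
    two_point_gains = lapply(obj$two_point_gains, function(g)
      list(gain = g$gain, offset = g$offset)),
    laser_references = lapply(obj$laser_references, as.numeric),
    taus = unlist(obj$taus), source = obj$source)
  m$created_at <- obj$created_at
  m
}

#' Save / load a trained regression bundle as versioned JSON
#'
#' @param bundle a `regression_bundle`.
#' @param path JSON file path.
#' @return `load_bundle()` returns the restored bundle.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "regression_bundle"))
  obj <- list(schema = "fiberspec/bundle/v1",
              family = bundle$family,
              models = lapply(bundle$models, as.list),
              feature_names = bundle$feature_names,
              chosen = bundle$chosen,
              grid = bundle$grid,
              folds = bundle$folds, split_seed = bundle$split_seed,
              cv_scores = bundle$cv_scores,
              test_scores = bundle$test_scores)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "fiberspec/bundle/v1"))
    stop("load_bundle: unknown schema: ", obj$schema, call. = FALSE)
  structure(list(family = obj$family,
                 models = lapply(obj$models, unlist),
                 feature_names = obj$feature_names,
                 selection = NULL,
                 grid = as.list(obj$grid),
                 chosen = as.list(obj$chosen),
                 folds = obj$folds, split_seed = obj$split_seed,
                 cv_scores = obj$cv_scores,
                 test_scores = obj$test_scores),
            class = "regression_bundle")
}

#' Read a pipeline configuration file
#'
#' Strict-schema YAML/JSON: only the sections `simulator`, `preprocess`,
#' `features`, `regress`, `monitor` (each with its module's known keys)
#' are accepted; unknown keys are an error. Missing keys take the
#' package defaults, and the fully materialized configuration is returned
#' (and echoed to the log by the command-line driver) for provenance.
#'
#' @param path YAML (or JSON) file.
#' @return nested list of settings with all defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  defaults <- list(
    simulator = list(levels = 5, n = 2000, replicates = 1, max_exposure = 20,
                     additive_sigma = 2, baseline_amplitude = 150,
                     baseline_decay = 0.002,
                     baseline_poly_coeffs = c(20, 0.02, -1e-4),
                     peak_fwhm = 30, base_amplitude = 1000,
                     cross_temperature_coeff = 0.005),
    preprocess = list(window = 11, order = 3, smoothness = 1e5,
                      asymmetry = 0.01, method = "adaptive"),
    features = list(search_radius = 15, threshold = 0.5,
                    kinds = c("height", "width", "area", "position",
                              "prominence")),
    regress = list(family = "bayesian", folds = 10, seed = 42,
                   fraction = 0.75),
    monitor = list(on_s = 5, off_s = 5, capacity = 100, window_points = 34,
                   scenario = "healthy"))
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad))
    stop("read_pipeline_config: unknown section(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (sec in names(cfg)) {
    badk <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
    if (length(badk))
      stop("read_pipeline_config: unknown key(s) in ", sec, ": ",
           paste(badk, collapse = ", "), call. = FALSE)
    defaults[[sec]] <- modifyList(defaults[[sec]], cfg[[sec]])
  }
  defaults
}
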