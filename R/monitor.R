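#' Circular readout buffer
#'
#' Fixed-capacity FIFO storage for per-biomarker readouts, mirroring the
#' instrument software's six circular buffers of 100 entries with a
#' 34-point (5-minute) display average.
#'
#' @param capacity maximum stored entries (oldest evicted first).
#' @param window_points number of most-recent entries averaged by
#'   [windowed_average()].
#' @return object of class `readout_buffer`.
#' @export
readout_buffer <- function(capacity = 100, window_points = 34) {
  if (capacity < 1 || window_points < 1)
    stop("readout_buffer: capacity and window_points must be >= 1", call. = FALSE)
  structure(list(capacity = as.integer(capacity),
                 window_points = as.integer(window_points),
                 times = numeric(0),
                 values = numeric(0)),
            class = "readout_buffer")
}

#' Push one reading into a circular buffer
#'
#' @param buffer a [readout_buffer()].
#' @param time timestamp, seconds.
#' @param value the reading.
#' @return the updated buffer (oldest entry evicted when full).
#' @export
buffer_push <- function(buffer, time, value) {
  buffer$times <- c(buffer$times, time)
  buffer$values <- c(buffer$values, value)
  if (length(buffer$values) > buffer$capacity) {
    keep <- seq.int(length(buffer$values) - buffer$capacity + 1L,
                    length(buffer$values))
    buffer$times <- buffer$times[keep]
    buffer$values <- buffer$values[keep]
  }
  buffer
}

#' @export
length.readout_buffer <- function(x) length(x$values)

#' Windowed display average of a readout buffer
#'
#' Arithmetic mean of the `min(window_points, n)` most recent entries;
#' `NA` for an empty buffer.
#'
#' @param buffer a [readout_buffer()].
#' @return the mean, or `NA_real_` when no data has arrived yet.
#' @export
windowed_average <- function(buffer) {
  n <- length(buffer$values)
  if (n == 0L) return(NA_real_)
  mean(tail(buffer$values, min(buffer$window_points, n)))
}

#' Streaming measurement loop
#'
#' Replays the instrument's readout cycle over a source of scans: for each
#' scan the fixed pipeline (denoise, baseline-correct, merge, extract,
#' photobleach-correct, predict) runs and the six predictions are pushed
#' into circular buffers; both the instantaneous and the windowed-average
#' series are emitted.
#'
#' @param source a `scan_set` (e.g. from [generate_scenario()]), or a
#'   [biomarker_state()] to monitor a constant state.
#' @param model a trained `regression_bundle`.
#' @param calibration optional [calibration_model()] (enables
#'   standardization when the model was trained on standardized features).
#' @param scans number of scans when `source` is a state.
#' @param schedule a [pulse_schedule()] (constant-state source only).
#' @param noise a [noise_config()] (constant-state source only).
#' @param channels channel set.
#' @param taus photobleaching constants for the correction step.
#' @param buffers optional list of six [readout_buffer()]s to continue
#'   filling.
#' @return object of class `monitor_series`: list with `series` (data.frame
#'   of timestamp, stage, per-biomarker instantaneous `{bm}` and averaged
#'   `{bm}_avg` columns) and `buffers` (final buffer states).
#' @export
run_monitor <- function(source, model, calibration = NULL, scans = 10,
                        schedule = pulse_schedule(),
                        noise = noiseless_config(),
                        channels = default_channels(),
                        taus = default_taus(), buffers = NULL) {
  if (inherits(source, "biomarker_state")) {
    ledger <- new_exposure_ledger()
    lst <- vector("list", scans)
    t <- 0
    for (i in seq_len(scans)) {
      sc <- run_scan(source, schedule, noise, ledger, channels, timestamp = t)
      ledger <- sc$ledger; t <- sc$timestamp
      lst[[i]] <- list(frames = sc$frames, state = source,
                       stage = "constant", time_s = t)
    }
    source <- structure(list(scans = lst, channels = channels,
                             meta = list()), class = "scan_set")
  }
  stopifnot(inherits(source, "scan_set"))
  if (is.null(buffers))
    buffers <- lapply(setNames(biomarker_names(), biomarker_names()),
                      function(.) readout_buffer())
  rows <- vector("list", length(source$scans))
  for (i in seq_along(source$scans)) {
    sc <- source$scans[[i]]
    m <- preprocess_scan(sc$frames, calibration = calibration)
    fv <- extract_features(m, channels)
    fv <- photobleach_correct(fv, taus)
    pred <- predict(model, fv)
    ts <- if (!is.null(sc$time_s)) sc$time_s else m$timestamp
    for (nm in biomarker_names())
      buffers[[nm]] <- buffer_push(buffers[[nm]], ts, pred[[nm]][1L])
    avg <- vapply(buffers, windowed_average, numeric(1))
    row <- data.frame(timestamp = ts,
                      stage = if (!is.null(sc$stage)) sc$stage else NA_character_)
    for (nm in biomarker_names()) {
      row[[nm]] <- pred[[nm]][1L]
      row[[paste0(nm, "_avg")]] <- avg[[nm]]
      if (!is.null(sc$state)) row[[paste0("true_", nm)]] <- sc$state[[nm]]
    }
    rows[[i]] <- row
  }
  structure(list(series = do.call(rbind, rows), buffers = buffers),
            class = "monitor_series")
}

#' @export
print.monitor_series <- function(x, ...) {
  cat(sprintf("<monitor_series> %d scans, %s\n", nrow(x$series),
              paste(unique(x$series$stage), collapse = " > ")))
  invisible(x)
}

#' Per-stage tracking errors and detection latency for a scenario run
#'
#' Scores the monitor's readout against the scenario's ground-truth
#' trajectory: per stage (and overall), MSE and MAE per biomarker, plus a
#' detection latency per stage - the time from stage onset until the
#' windowed-average readout first crosses halfway from the previous
#' stage's target to the new target (NA when a biomarker's target does not
#' change, reported as the max over the biomarkers that do change).
#'
#' @param monitor a `monitor_series` from [run_monitor()] over a scenario
#'   `scan_set` (needs `true_*` columns and stages).
#' @param use_average score the windowed-average readout instead of the
#'   instantaneous one.
#' @return list with `per_stage` (data.frame of stage x biomarker MSE/MAE),
#'   `overall` (data.frame), and `latency_s` (named numeric per stage).
#' @export
track_scenario <- function(monitor, use_average = FALSE) {
  s <- monitor$series
  if (!"true_temperature" %in% names(s))
    stop("track_scenario: monitor series has no ground-truth columns", call. = FALSE)
  suffix <- if (use_average) "_avg" else ""
  pred <- s[, paste0(biomarker_names(), suffix), drop = FALSE]
  names(pred) <- biomarker_names()
  truth <- s[, paste0("true_", biomarker_names()), drop = FALSE]
  names(truth) <- biomarker_names()
  overall <- suppressWarnings(
    score_predictions(pred, truth))[, c("biomarker", "mse", "mae")]
  stages <- unique(s$stage)
  per_stage <- do.call(rbind, lapply(stages, function(st) {
    i <- s$stage == st
    cbind(stage = st,
          suppressWarnings(score_predictions(pred[i, , drop = FALSE],
            truth[i, , drop = FALSE]))[, c("biomarker", "mse", "mae")])
  }))
  # detection latency from the averaged readout
  lat <- setNames(rep(NA_real_, length(stages)), stages)
  for (k in seq_along(stages)) {
    i <- which(s$stage == stages[k])
    onset <- s$timestamp[i[1L]]
    prev <- if (k == 1L) unclass(healthy_state()) else
      vapply(biomarker_names(), function(nm)
        truth[[nm]][tail(which(s$stage == stages[k - 1L]), 1L)], numeric(1))
    tgt <- vapply(biomarker_names(), function(nm) truth[[nm]][tail(i, 1L)],
                  numeric(1))
    lat_bm <- c()
    for (nm in biomarker_names()) {
      if (abs(tgt[[nm]] - prev[[nm]]) < 1e-9) next
      halfway <- (prev[[nm]] + tgt[[nm]]) / 2
      av <- s[[paste0(nm, "_avg")]][i]
      crossed <- if (tgt[[nm]] > prev[[nm]]) av >= halfway else av <= halfway
      lat_bm[nm] <- if (any(crossed))
        s$timestamp[i[which(crossed)[1L]]] - onset else NA_real_
    }
    if (length(lat_bm)) lat[k] <- suppressWarnings(max(lat_bm, na.rm = TRUE))
  }
  list(per_stage = per_stage, overall = overall, latency_s = lat)
}

#' Spike-recovery rate
#'
#' The fraction of a known spiked increment that the readout recovers:
#' 100 * (spiked - baseline) / spike_amount, in percent.
#'
#' @param baseline_readout readout before the spike.
#' @param spiked_readout readout after the spike.
#' @param spike_amount spiked increment (> 0), same units.
#' @return recovery rate in percent.
#' @examples
#' recovery_rate(140, 159, 20)  # 95
#' @export
recovery_rate <- function(baseline_readout, spiked_readout, spike_amount) {
  if (any(spike_amount <= 0))
    stop("recovery_rate: spike_amount must be positive", call. = FALSE)
  100 * (spiked_readout - baseline_readout) / spike_amount
}
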