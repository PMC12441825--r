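# EEG band-limiting, resampling, epoching and ROI averaging.
#
# The pipeline consumes already artifact-cleaned continuous data (ICA and
# bad-channel handling are ingest-time responsibilities of the recording
# pipeline); here the contract is deterministic band-limiting (0.1-45 Hz
# zero-phase Butterworth), resampling to 256 Hz and event-locked epoching.

#' Band-limit, resample and epoch continuous multichannel data
#'
#' Applies a zero-phase Butterworth high-pass (0.1 Hz) and low-pass (45 Hz)
#' to each sensor, resamples to the target rate (linear interpolation on the
#' band-limited signal), and extracts epochs around the requested event
#' times. Events whose epoch would extend beyond the recording are dropped
#' and logged in the result's `exclusions`.
#'
#' @param continuous sensors x samples numeric matrix.
#' @param rate_hz sampling rate of `continuous`.
#' @param events_ms event times in ms from recording start (e.g. target or
#'   motor-cue onsets).
#' @param config a [pipeline_config()]; uses `eeg_highpass_hz`,
#'   `eeg_lowpass_hz`, `eeg_filter_order`, `eeg_rate_hz`, `eeg_window_ms`.
#' @param sensor_labels optional sensor names.
#' @param schedule optional `trial_schedule` (must match the retained
#'   events).
#' @return an [epoched_dataset()] with an `exclusions` data frame attached
#'   as an attribute.
#' @export
epoch_eeg <- function(continuous, rate_hz, events_ms,
                      config = pipeline_config(), sensor_labels = NULL,
                      schedule = NULL) {
  stopifnot(is.matrix(continuous))
  p <- nrow(continuous)
  filtered <- t(apply(continuous, 1, butter_filtfilt, rate_hz = rate_hz,
                      highpass_hz = config$eeg_highpass_hz,
                      lowpass_hz = config$eeg_lowpass_hz,
                      order = config$eeg_filter_order))

  # resample each sensor onto the target-rate grid
  out_rate <- config$eeg_rate_hz
  t_in <- (seq_len(ncol(continuous)) - 1) * 1000 / rate_hz
  t_out <- seq(0, max(t_in), by = 1000 / out_rate)
  res <- t(apply(filtered, 1, function(ch) {
    stats::approx(t_in, ch, xout = t_out, rule = 2)$y
  }))

  win <- config$eeg_window_ms
  n_time <- round(diff(win) / 1000 * out_rate)
  offsets <- round(win[1] / 1000 * out_rate) + seq_len(n_time) - 1L
  epochs <- list(); kept <- integer(0)
  excl <- data.frame(event = integer(0), reason = character(0))
  for (j in seq_along(events_ms)) {
    i0 <- round(events_ms[j] / 1000 * out_rate) + 1L
    idx <- i0 + offsets
    if (idx[1] < 1L || idx[length(idx)] > ncol(res)) {
      excl <- rbind(excl, data.frame(event = j, reason = "epoch outside recording"))
      next
    }
    epochs[[length(epochs) + 1L]] <- res[, idx, drop = FALSE]
    kept <- c(kept, j)
  }
  if (!length(epochs)) stop("no epochs could be extracted.", call. = FALSE)
  data <- array(0, c(length(epochs), p, n_time))
  for (j in seq_along(epochs)) data[j, , ] <- epochs[[j]]
  if (!is.null(schedule)) schedule <- schedule[kept, , drop = FALSE]
  ds <- epoched_dataset(data, out_rate, win, sensor_labels = sensor_labels,
                        schedule = schedule)
  attr(ds, "exclusions") <- excl
  attr(ds, "events_kept") <- kept
  ds
}

#' Per-condition ERP over a region of interest
#'
#' Averages the epoched data over the ROI sensors (arithmetic mean), then
#' over trials within each 2x2 condition cell, yielding one ERP time course
#' per cell.
#'
#' @param dataset an [epoched_dataset()] with a schedule.
#' @param roi character vector of sensor labels (default [default_roi()]).
#' @return matrix 4 x timepoints with rows `VEME, VEMU, VUME, VUMU`.
#' @export
roi_mean <- function(dataset, roi = default_roi()) {
  unknown <- setdiff(roi, dataset$sensor_labels)
  if (length(unknown)) {
    stop("unknown ROI sensor label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(dataset$schedule)) {
    stop("dataset has no schedule; cell-wise ERPs are undefined.", call. = FALSE)
  }
  sensor_idx <- match(roi, dataset$sensor_labels)
  # mean over ROI sensors per trial and timepoint
  roi_tc <- apply(dataset$data[, sensor_idx, , drop = FALSE], c(1, 3), mean)
  cells <- cell_labels(dataset$schedule)
  out <- matrix(NA_real_, 4, dim(dataset$data)[3],
                dimnames = list(CELL_LEVELS, NULL))
  for (cl in CELL_LEVELS) {
    sel <- cells == cl
    if (any(sel)) out[cl, ] <- colMeans(roi_tc[sel, , drop = FALSE])
  }
  out
}
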