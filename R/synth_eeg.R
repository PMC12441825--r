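# Synthetic orientation-tuned EEG epochs with known ground truth.
#
# The generator inverts the decoding pipeline's own forward model: sensor
# data are W c(theta) scaled by a temporal profile, plus spatially
# correlated Gaussian noise. Recovery of the injected orientations through
# the inverted encoding model is the closed-loop consistency check for both
# halves.

# 64-channel 10-20/10-10 montage (actiCap layout, FCz online reference).
MONTAGE_64 <- c(
  "Fp1", "Fz", "F3", "F7", "FT9", "FC5", "FC1", "C3", "T7", "TP9", "CP5",
  "CP1", "Pz", "P3", "P7", "O1", "Oz", "O2", "P4", "P8", "TP10", "CP6",
  "CP2", "Cz", "C4", "T8", "FT10", "FC6", "FC2", "F4", "F8", "Fp2", "AF7",
  "AF3", "AFz", "F1", "F5", "FT7", "FC3", "C1", "C5", "TP7", "CP3", "P1",
  "P5", "PO7", "PO3", "POz", "PO4", "PO8", "P6", "P2", "CPz", "CP4", "TP8",
  "C6", "C2", "FC4", "FT8", "F6", "AF8", "AF4", "F2", "Iz")

default_sensor_labels <- function(n_sensors) {
  if (n_sensors <= length(MONTAGE_64)) {
    MONTAGE_64[seq_len(n_sensors)]
  } else {
    c(MONTAGE_64, paste0("EXT", seq_len(n_sensors - length(MONTAGE_64))))
  }
}

#' Epoched multichannel dataset
#'
#' Container for epoched sensor data: a trials x sensors x timepoints array
#' with its sampling rate, epoch window, sensor labels and trial schedule.
#' The number of timepoints must equal
#' `round(diff(epoch_window_ms) / 1000 * sampling_rate_hz)` and the trials
#' dimension must match the schedule.
#'
#' @param data numeric array, trials x sensors x timepoints.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param epoch_window_ms length-2 epoch window in ms relative to the event.
#' @param sensor_labels character vector of sensor names (default: 10-20
#'   montage labels).
#' @param schedule the `trial_schedule` the trials follow.
#' @param ground_truth optional list of generative parameters (synthetic data
#'   only).
#' @return an `epoched_dataset`.
#' @export
epoched_dataset <- function(data, sampling_rate_hz, epoch_window_ms,
                            sensor_labels = NULL, schedule = NULL,
                            ground_truth = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n_time_expected <- round(diff(epoch_window_ms) / 1000 * sampling_rate_hz)
  if (dim(data)[3] != n_time_expected) {
    stop(sprintf("data has %d timepoints but the window/rate imply %d.",
                 dim(data)[3], n_time_expected), call. = FALSE)
  }
  if (!is.null(schedule) && dim(data)[1] != nrow(schedule)) {
    stop("trials dimension does not match the schedule.", call. = FALSE)
  }
  if (is.null(sensor_labels)) sensor_labels <- default_sensor_labels(dim(data)[2])
  if (length(sensor_labels) != dim(data)[2]) {
    stop("sensor_labels length does not match the sensor dimension.", call. = FALSE)
  }
  times <- epoch_window_ms[1] + (seq_len(dim(data)[3]) - 1) * 1000 / sampling_rate_hz
  structure(list(data = data, sampling_rate_hz = sampling_rate_hz,
                 epoch_window_ms = epoch_window_ms, time_ms = times,
                 sensor_labels = sensor_labels, schedule = schedule,
                 ground_truth = ground_truth),
            class = "epoched_dataset")
}

#' @export
print.epoched_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoched dataset: %d trials x %d sensors x %d timepoints @ %g Hz, window [%g, %g] ms\n",
              d[1], d[2], d[3], x$sampling_rate_hz,
              x$epoch_window_ms[1], x$epoch_window_ms[2]))
  if (!is.null(x$ground_truth)) cat("  synthetic (ground truth attached)\n")
  invisible(x)
}

#' Generative tuning configuration for synthetic EEG
#'
#' Parameters of the forward-model generator: ground-truth sensor weights for
#' the five orientation channels (drawn once per dataset from smoothed
#' standard normals if not supplied), a unit-amplitude temporal profile over
#' the signal window, a spatially correlated noise covariance with
#' exponential decay over sensor index distance (`corr(i, j) =
#' exp(-|i - j| / noise_lambda)`, emulating high correlations between
#' neighbouring sensors), and the signal-to-noise ratio defined as the RMS of
#' the orientation-tuned signal inside the signal window over the RMS of the
#' noise.
#'
#' @param n_sensors number of sensors (default 64).
#' @param basis the [iem_basis()] generating channel responses.
#' @param signal_window_ms window of orientation-tuned signal (default
#'   `c(50, 300)` ms post-target).
#' @param noise_lambda spatial correlation length in sensor-index units.
#' @param snr nonnegative signal-to-noise RMS ratio.
#' @param forward_weights optional fixed sensors x channels matrix.
#' @return a `tuning_config`.
#' @export
tuning_config <- function(n_sensors = 64, basis = iem_basis(),
                          signal_window_ms = c(50, 300), noise_lambda = 2,
                          snr = 1, forward_weights = NULL) {
  check_scalar(snr, "snr", function(x) is.numeric(x) && x >= 0, "a nonnegative number")
  idx <- seq_len(n_sensors)
  noise_cov <- exp(-abs(outer(idx, idx, "-")) / noise_lambda)
  structure(list(n_sensors = n_sensors, basis = basis,
                 signal_window_ms = signal_window_ms,
                 noise_covariance = noise_cov, noise_lambda = noise_lambda,
                 snr = snr, forward_weights = forward_weights),
            class = "tuning_config")
}

# Raised-cosine temporal gain in [0, 1], nonzero inside the signal window.
temporal_profile <- function(time_ms, window_ms) {
  p <- numeric(length(time_ms))
  inside <- time_ms >= window_ms[1] & time_ms <= window_ms[2]
  p[inside] <- sin(pi * (time_ms[inside] - window_ms[1]) / diff(window_ms))^2
  p
}

# Smooth a sensors x channels weight matrix across neighbouring sensors
# (moving average of width 3), mimicking spatially spread scalp topographies.
smooth_weights <- function(w) {
  n <- nrow(w)
  out <- w
  if (n >= 3) {
    out[2:(n - 1), ] <- (w[1:(n - 2), ] + w[2:(n - 1), ] + w[3:n, ]) / 3
  }
  out
}

#' Simulate orientation-tuned epoched EEG
#'
#' Generates `data[trial, , t] = alpha * W c(theta_trial) * profile(t) +
#' noise`, where `c(theta)` are the basis channel responses to the trial's
#' target orientation, `W` are the ground-truth forward weights, the profile
#' is a raised cosine over the signal window, and the noise is spatially
#' correlated Gaussian (temporally white). `alpha` scales the signal so that
#' its RMS inside the signal window equals `snr` times the noise RMS;
#' `snr = 0` yields pure noise.
#'
#' @param schedule a `trial_schedule` supplying trials and orientations.
#' @param tuning a [tuning_config()].
#' @param seed integer seed; output is a pure function of arguments and seed.
#' @param sampling_rate_hz sampling rate (default 256 Hz).
#' @param epoch_window_ms epoch window (default `c(-200, 500)` ms).
#' @return an [epoched_dataset()] with `ground_truth` holding the drawn
#'   weights, profile, covariance and snr.
#' @export
simulate_eeg <- function(schedule, tuning = tuning_config(), seed = 1L,
                         sampling_rate_hz = 256, epoch_window_ms = c(-200, 500)) {
  if (nrow(schedule) == 0) stop("schedule is empty.", call. = FALSE)
  n_trials <- nrow(schedule)
  p <- tuning$n_sensors
  n_time <- round(diff(epoch_window_ms) / 1000 * sampling_rate_hz)
  times <- epoch_window_ms[1] + (seq_len(n_time) - 1) * 1000 / sampling_rate_hz
  prof <- temporal_profile(times, tuning$signal_window_ms)

  chol_noise <- tryCatch(chol(tuning$noise_covariance), error = function(e) {
    stop("noise covariance is not symmetric positive definite.", call. = FALSE)
  })

  with_seed(seed, {
    W <- tuning$forward_weights
    if (is.null(W)) {
      W <- smooth_weights(matrix(stats::rnorm(p * length(tuning$basis$preferred_deg)),
                                 nrow = p))
    }
    cmat <- channel_responses(schedule$target_orientation_deg, tuning$basis)
    sig_amp <- W %*% cmat                        # sensors x trials
    # scale so RMS of the signal inside the window is snr * noise RMS (= 1)
    in_win <- prof > 0
    rms_sig <- sqrt(mean(sig_amp^2) * mean(prof[in_win]^2))
    alpha <- if (rms_sig > 0 && tuning$snr > 0) tuning$snr / rms_sig else 0

    data <- array(0, c(n_trials, p, n_time))
    for (j in seq_len(n_trials)) {
      noise <- crossprod(chol_noise, matrix(stats::rnorm(p * n_time), p, n_time))
      data[j, , ] <- alpha * tcrossprod(sig_amp[, j], prof) + noise
    }
    epoched_dataset(data, sampling_rate_hz, epoch_window_ms,
                    schedule = schedule,
                    ground_truth = list(forward_weights = W,
                                        temporal_profile = prof,
                                        signal_window_ms = tuning$signal_window_ms,
                                        noise_covariance = tuning$noise_covariance,
                                        snr = tuning$snr, alpha = alpha,
                                        seed = seed))
  })
}
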