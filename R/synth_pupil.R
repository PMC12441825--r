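# Synthetic continuous pupil-diameter traces.
#
# A slow baseline drift plus an event-locked dilation per trial (gamma-shaped
# impulse response scaled by the trial's condition-cell amplitude), white
# measurement noise, missing-sample blink segments and sporadic outlier
# spikes. Provides known ground truth for the preprocessing pipeline.

#' Ground-truth pupil generative parameters
#'
#' @param dilation_amplitude_per_cell peak-normalised dilation amplitude in z
#'   units per cell (order `VEME, VEMU, VUME, VUMU`; length 4 or 1). Defaults
#'   give motor-expected trials the larger dilation.
#' @param kernel_latency_ms time-to-peak of the dilation impulse response.
#' @param kernel_shape shape parameter of the gamma-form kernel.
#' @param kernel_duration_ms kernel support length.
#' @param blink_rate_hz expected blink rate (events per second).
#' @param blink_duration_ms length-2 range of blink durations.
#' @param outlier_rate per-sample probability of an outlier spike.
#' @param baseline_drift_sd standard deviation of the slow baseline drift.
#' @param noise_sd standard deviation of white measurement noise.
#' @return a `pupil_truth`.
#' @export
pupil_truth <- function(dilation_amplitude_per_cell = c(0.5, 0.3, 0.5, 0.3),
                        kernel_latency_ms = 930, kernel_shape = 10.1,
                        kernel_duration_ms = 2500,
                        blink_rate_hz = 0.2, blink_duration_ms = c(100, 300),
                        outlier_rate = 1e-4, baseline_drift_sd = 0.3,
                        noise_sd = 0.05) {
  amp <- rep_len(dilation_amplitude_per_cell, 4L)
  names(amp) <- CELL_LEVELS
  if (blink_rate_hz < 0 || outlier_rate < 0 || baseline_drift_sd < 0) {
    stop("rates and spreads must be non-negative.", call. = FALSE)
  }
  structure(list(dilation_amplitude_per_cell = amp,
                 kernel_latency_ms = kernel_latency_ms,
                 kernel_shape = kernel_shape,
                 kernel_duration_ms = kernel_duration_ms,
                 blink_rate_hz = blink_rate_hz,
                 blink_duration_ms = blink_duration_ms,
                 outlier_rate = outlier_rate,
                 baseline_drift_sd = baseline_drift_sd,
                 noise_sd = noise_sd),
            class = "pupil_truth")
}

# Gamma-form pupil impulse response h(t) = t^s exp(-s t / t_peak), peak at
# t_peak, normalised to unit peak.
pupil_kernel <- function(sampling_rate_hz, latency_ms, shape, duration_ms) {
  t_ms <- seq(0, duration_ms, by = 1000 / sampling_rate_hz)
  h <- t_ms^shape * exp(-shape * t_ms / latency_ms)
  h / max(h)
}

#' Simulate a continuous pupil trace with blinks and outliers
#'
#' Builds a continuous diameter trace around one target-onset event per
#' trial: baseline drift (smoothed random walk) + per-trial dilation kernel
#' scaled by the trial cell's amplitude + white noise. Blink segments
#' (mutually disjoint) are marked missing; outlier samples receive large
#' spikes. Events and blink annotations are returned alongside the trace.
#'
#' @param schedule a `trial_schedule`.
#' @param truth a [pupil_truth()].
#' @param sampling_rate_hz sampling rate, at least 250 Hz (default 1000).
#' @param trial_spacing_ms spacing between consecutive target onsets.
#' @param seed integer seed.
#' @return a `pupil_trace`: list with `time_ms`, `diameter`, `missing`
#'   (logical), `outliers` (injected outlier sample indices), `events`
#'   (data frame: `trial_index`, `time_ms`, `cell`),
#'   `blinks` (data frame: `onset_ms`, `offset_ms`), `sampling_rate_hz`,
#'   `clean_diameter` (ground-truth trace before blinks/outliers/noise) and
#'   `truth`.
#' @export
simulate_pupil <- function(schedule, truth = pupil_truth(),
                           sampling_rate_hz = 1000, trial_spacing_ms = 4000,
                           seed = 1L) {
  if (sampling_rate_hz < 250) {
    stop("sampling_rate_hz must be at least 250 Hz.", call. = FALSE)
  }
  n_trials <- nrow(schedule)
  cells <- cell_labels(schedule)
  dt_ms <- 1000 / sampling_rate_hz
  pad_ms <- 2000
  total_ms <- 2 * pad_ms + n_trials * trial_spacing_ms
  n <- floor(total_ms / dt_ms)
  time_ms <- (seq_len(n) - 1) * dt_ms
  event_ms <- pad_ms + (seq_len(n_trials) - 1) * trial_spacing_ms

  kern <- pupil_kernel(sampling_rate_hz, truth$kernel_latency_ms,
                       truth$kernel_shape, truth$kernel_duration_ms)

  with_seed(seed, {
    # slow drift: heavily smoothed random walk rescaled to the target SD
    drift <- cumsum(stats::rnorm(n))
    win <- max(1L, round(sampling_rate_hz))   # 1 s moving average
    drift <- stats::filter(drift, rep(1 / win, win), sides = 2)
    drift[is.na(drift)] <- 0
    if (stats::sd(drift) > 0) {
      drift <- (drift - mean(drift)) / stats::sd(drift) * truth$baseline_drift_sd
    }

    clean <- as.numeric(drift)
    amp <- truth$dilation_amplitude_per_cell[as.integer(cells)]
    for (j in seq_len(n_trials)) {
      i0 <- round(event_ms[j] / dt_ms) + 1L
      span <- i0:min(n, i0 + length(kern) - 1L)
      clean[span] <- clean[span] + amp[j] * kern[seq_along(span)]
    }

    diameter <- clean + stats::rnorm(n, sd = truth$noise_sd)

    # disjoint blink segments marked missing
    missing <- logical(n)
    n_blinks <- stats::rpois(1, truth$blink_rate_hz * total_ms / 1000)
    blinks <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0))
    tries <- 0L
    while (nrow(blinks) < n_blinks && tries < 50L * max(1L, n_blinks)) {
      tries <- tries + 1L
      dur <- stats::runif(1, truth$blink_duration_ms[1], truth$blink_duration_ms[2])
      onset <- stats::runif(1, 0, total_ms - dur)
      i1 <- max(1L, round(onset / dt_ms) + 1L)
      i2 <- min(n, round((onset + dur) / dt_ms) + 1L)
      # keep blinks disjoint with a one-sample gap so segments stay countable
      lo <- max(1L, i1 - 1L)
      hi <- min(n, i2 + 1L)
      if (!any(missing[lo:hi])) {
        missing[i1:i2] <- TRUE
        blinks <- rbind(blinks, data.frame(onset_ms = time_ms[i1],
                                           offset_ms = time_ms[i2]))
      }
    }
    diameter[missing] <- NA_real_

    # outlier spikes on the surviving samples, positions recorded as truth
    out_idx <- which(!missing & stats::runif(n) < truth$outlier_rate)
    if (length(out_idx)) {
      diameter[out_idx] <- diameter[out_idx] +
        sample(c(-1, 1), length(out_idx), replace = TRUE) *
        stats::runif(length(out_idx), 5, 10)
    }

    structure(list(time_ms = time_ms, diameter = diameter, missing = missing,
                   outliers = out_idx,
                   events = data.frame(trial_index = schedule$trial_index,
                                       time_ms = event_ms, cell = cells),
                   blinks = blinks[order(blinks$onset_ms), , drop = FALSE],
                   sampling_rate_hz = sampling_rate_hz,
                   clean_diameter = clean, truth = truth),
              class = "pupil_trace")
  })
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("Pupil trace: %.1f s @ %g Hz, %d events, %d blink segments, %.2f%% missing\n",
              max(x$time_ms) / 1000, x$sampling_rate_hz, nrow(x$events),
              nrow(x$blinks), 100 * mean(x$missing)))
  invisible(x)
}
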