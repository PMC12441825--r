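# Deterministic pupillometry preprocessing.
#
# Fixed step order: (1) blink removal with a 100 ms buffer on each side,
# (2) outlier removal at |x - median| / MAD > 2.5, (3) linear interpolation
# over missing runs, (4) zero-phase first-order Butterworth filtering,
# (5) z-scoring of the continuous trace, (6) epoching to [-500, 1500] ms
# around target onset, (7) down-sampling to 125 Hz (250 samples per epoch).

PUPIL_STEPS <- c("blink_buffer", "mad_outliers", "interpolate", "filter",
                 "zscore", "epoch", "downsample")

# Expand TRUE runs of a logical mask by buf samples on each side.
expand_mask <- function(mask, buf) {
  if (!any(mask) || buf <= 0) return(mask)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- mask
  for (i in which(r$values)) {
    out[max(1L, starts[i] - buf):min(length(mask), ends[i] + buf)] <- TRUE
  }
  out
}

# Zero-phase Butterworth filtering of one vector; high and/or low cutoff.
butter_filtfilt <- function(x, rate_hz, highpass_hz, lowpass_hz, order) {
  nyq <- rate_hz / 2
  if (!is.null(lowpass_hz) && lowpass_hz >= nyq) {
    warning(sprintf("low-pass cutoff %g Hz is at or above Nyquist (%g Hz); skipping the low-pass stage.",
                    lowpass_hz, nyq), call. = FALSE)
    lowpass_hz <- NULL
  }
  if (!is.null(highpass_hz) && highpass_hz > 0) {
    hp <- signal::butter(order, highpass_hz / nyq, type = "high")
    x <- signal::filtfilt(hp, x)
  }
  if (!is.null(lowpass_hz)) {
    lp <- signal::butter(order, lowpass_hz / nyq, type = "low")
    x <- signal::filtfilt(lp, x)
  }
  x
}

#' Preprocess a continuous pupil trace into z-scored epochs
#'
#' Applies the fixed preprocessing sequence (blink buffering, MAD outlier
#' rejection, interpolation, zero-phase Butterworth filtering, z-scoring,
#' epoching, down-sampling) to a continuous diameter trace. The executed
#' step order is recorded in the result. With the default configuration the
#' epochs cover [-500, 1500] ms at 125 Hz: exactly 250 samples, none
#' missing. Epochs that extend beyond the trace, or whose samples were
#' entirely missing before interpolation, are excluded and logged rather
#' than raising an error.
#'
#' The default filter cutoffs (15.6-500 Hz) are far above pupil dynamics; a
#' warning is emitted when they are used (see [pipeline_config()]).
#'
#' @param trace a `pupil_trace` (see [simulate_pupil()]), or a list with
#'   `time_ms`, `diameter`, optional `missing`, `events`, `sampling_rate_hz`.
#' @param config a [pipeline_config()].
#' @return a `pupil_epochs`: list with `data` (trials x timepoints),
#'   `time_ms` (epoch axis), `trial_index`, `exclusions` (data frame with
#'   `trial_index`, `reason`), `steps`, `config`.
#' @export
preprocess_pupil <- function(trace, config = pipeline_config()) {
  x <- trace$diameter
  n <- length(x)
  rate <- trace$sampling_rate_hz
  dt_ms <- 1000 / rate
  missing <- if (!is.null(trace$missing)) trace$missing else is.na(x)
  missing <- missing | is.na(x)
  steps <- character(0)

  # 1. blink samples +/- buffer marked missing
  buf <- round(config$blink_buffer_ms / dt_ms)
  missing <- expand_mask(missing, buf)
  steps <- c(steps, "blink_buffer")

  # 2. MAD outliers among the remaining samples
  good <- x[!missing]
  med <- stats::median(good)
  mad_val <- stats::mad(good)
  if (mad_val > 0) {
    out <- !missing & abs(x - med) / mad_val > config$mad_threshold
    missing <- missing | out
  }
  steps <- c(steps, "mad_outliers")

  # 3. linear interpolation over missing runs
  x[missing] <- NA_real_
  if (any(missing)) {
    if (all(missing)) stop("the entire trace is missing.", call. = FALSE)
    x <- stats::approx(which(!missing), x[!missing], xout = seq_len(n),
                       rule = 2)$y
  }
  steps <- c(steps, "interpolate")

  # 4. zero-phase Butterworth filtering
  if (isTRUE(config$pupil_filter)) {
    if (identical(config$pupil_highpass_hz, 15.6) &&
        identical(config$pupil_lowpass_hz, 500)) {
      warning(paste("pupil filter passband 15.6-500 Hz lies above pupil dynamics",
                    "(< 4 Hz) and will remove nearly all signal of interest;",
                    "set pupil_highpass_hz/pupil_lowpass_hz deliberately."),
              call. = FALSE)
    }
    x <- butter_filtfilt(x, rate, config$pupil_highpass_hz,
                         config$pupil_lowpass_hz, config$pupil_filter_order)
    steps <- c(steps, "filter")
  } else {
    steps <- c(steps, "filter")   # stage present in the order, disabled
  }

  # 5. z-score the continuous trace
  x <- (x - mean(x)) / stats::sd(x)
  steps <- c(steps, "zscore")

  # 6. epoch around target onsets; 7. down-sample
  win <- config$pupil_window_ms
  n_native <- round(diff(win) / dt_ms)
  stride <- rate / config$pupil_rate_hz
  if (abs(stride - round(stride)) > 1e-9) {
    stop("sampling rate must be an integer multiple of the target pupil rate.",
         call. = FALSE)
  }
  stride <- as.integer(round(stride))
  take <- seq(1L, n_native, by = stride)
  epoch_time <- win[1] + (take - 1L) * dt_ms

  events <- trace$events
  rows <- list(); kept <- integer(0)
  excl <- data.frame(trial_index = integer(0), reason = character(0))
  for (j in seq_len(nrow(events))) {
    i0 <- round(events$time_ms[j] / dt_ms) + 1L
    idx <- i0 + round(win[1] / dt_ms) + seq_len(n_native) - 1L
    if (idx[1] < 1L || idx[length(idx)] > n) {
      excl <- rbind(excl, data.frame(trial_index = events$trial_index[j],
                                     reason = "epoch outside trace"))
      next
    }
    if (all(missing[idx])) {
      excl <- rbind(excl, data.frame(trial_index = events$trial_index[j],
                                     reason = "epoch entirely missing"))
      next
    }
    rows[[length(rows) + 1L]] <- x[idx][take]
    kept <- c(kept, events$trial_index[j])
  }
  steps <- c(steps, "epoch", "downsample")

  structure(list(data = do.call(rbind, rows), time_ms = epoch_time,
                 trial_index = kept, exclusions = excl, steps = steps,
                 missing_mask = missing, rate_hz = config$pupil_rate_hz,
                 config = config),
            class = "pupil_epochs")
}

#' @export
print.pupil_epochs <- function(x, ...) {
  cat(sprintf("Pupil epochs: %d trials x %d samples @ %g Hz; %d excluded\n",
              nrow(x$data), ncol(x$data), x$rate_hz, nrow(x$exclusions)))
  invisible(x)
}
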