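# Pupil preprocessing, EEG epoching, ROI averaging, and plain-text I/O.

clean_trace <- function(n_trials = 6, seed = 1) {
  sched <- generate_schedule(1, 16, seed = seed)[seq_len(n_trials), ]
  class(sched) <- c("trial_schedule", "data.frame")
  simulate_pupil(sched, pupil_truth(blink_rate_hz = 0, outlier_rate = 0,
                                    noise_sd = 0.02),
                 seed = seed)
}

soft_config <- function(...) {
  pipeline_config(pupil_highpass_hz = NULL, pupil_lowpass_hz = 4, ...)
}

test_that("with filtering disabled the pupil pipeline is z-score + epoch + downsample", {
  tr <- clean_trace(seed = 2)
  # the outlier stage is given an infinite threshold so the identity path
  # isolates z-scoring, epoching and down-sampling
  pe <- preprocess_pupil(tr, soft_config(pupil_filter = FALSE,
                                         mad_threshold = Inf))
  expect_equal(ncol(pe$data), 250)

  # manual reference: z-score the trace, cut epochs, take every 8th sample
  z <- (tr$diameter - mean(tr$diameter)) / sd(tr$diameter)
  for (j in seq_len(nrow(tr$events))) {
    i0 <- round(tr$events$time_ms[j]) + 1
    idx <- seq(i0 - 500, by = 8, length.out = 250)
    expect_equal(pe$data[j, ], z[idx], tolerance = 1e-10)
  }
  # executed step order is the documented pipeline order
  expect_equal(pe$steps, c("blink_buffer", "mad_outliers", "interpolate",
                           "filter", "zscore", "epoch", "downsample"))
})

test_that("blinks are buffered by 100 ms per side and fully interpolated", {
  tr <- clean_trace(seed = 3)
  blink_idx <- 5000:5150                  # 151 samples ~ 150 ms blink
  tr$diameter[blink_idx] <- NA
  tr$missing[blink_idx] <- TRUE
  pe <- preprocess_pupil(tr, soft_config(pupil_filter = FALSE,
                                         mad_threshold = Inf))

  expect_true(all(is.finite(pe$data)))    # zero missing samples in the output
  # interpolated span = blink span + 100 ms buffer on each side
  expect_equal(sum(pe$missing_mask), length(blink_idx) + 200)
  expect_equal(range(which(pe$missing_mask)), c(4900, 5250))
})

test_that("MAD outliers are replaced and leave the output in the clean range", {
  tr <- clean_trace(seed = 4)
  clean_out <- preprocess_pupil(tr, soft_config())$data
  spike_at <- 7000
  tr2 <- tr
  mad_val <- stats::mad(tr2$diameter)
  tr2$diameter[spike_at] <- stats::median(tr2$diameter) + 10 * mad_val
  spiked_out <- preprocess_pupil(tr2, soft_config())$data
  expect_true(pe_removed <- spike_at %in% which(preprocess_pupil(tr2, soft_config())$missing_mask))
  expect_lt(max(abs(spiked_out)), max(abs(clean_out)) + 3 * stats::sd(clean_out))
})

test_that("the preprocessed epochs track the noiseless dilation ground truth", {
  tr <- clean_trace(n_trials = 12, seed = 5)
  # no blinks or outliers were injected, so the rejection stages are idled
  pe <- preprocess_pupil(tr, soft_config(mad_threshold = Inf))
  # low-pass the clean ground-truth trace the same way, then epoch/downsample
  lp <- signal::butter(1, 4 / 500, type = "low")
  zt <- signal::filtfilt(lp, tr$clean_diameter)
  zt <- (zt - mean(zt)) / sd(zt)
  for (j in seq_len(nrow(pe$data))) {
    i0 <- round(tr$events$time_ms[j]) + 1
    idx <- seq(i0 - 500, by = 8, length.out = 250)
    expect_gt(stats::cor(pe$data[j, ], zt[idx]), 0.99)
  }
})

test_that("per-cell dilation amplitude differences survive preprocessing", {
  sched <- generate_schedule(10, 72, seed = 6)
  matched <- match_trials(sched)          # 45 trials per cell
  truth <- pupil_truth(dilation_amplitude_per_cell = c(0.5, 0, 0.5, 0),
                       blink_rate_hz = 0.05)
  tr <- simulate_pupil(matched, truth, seed = 6)
  pe <- preprocess_pupil(tr, soft_config())
  cells <- cell_labels(matched)[match(pe$trial_index, matched$trial_index)]
  me <- grepl("ME", cells)

  # epoch-mean difference around the kernel peak, converted back from
  # z units with the spread of the filtered trace (reconstructed test-side)
  win <- pe$time_ms >= 700 & pe$time_ms <= 1200
  diff_z <- mean(pe$data[me, win]) - mean(pe$data[!me, win])
  x <- tr$diameter
  miss <- tr$missing | is.na(x)
  x <- stats::approx(which(!miss), x[!miss], xout = seq_along(x), rule = 2)$y
  xf <- signal::filtfilt(signal::butter(1, 4 / 500, "low"), x)
  diff_raw <- diff_z * stats::sd(xf)

  # ground truth: amplitude difference times the kernel mean over the window
  tk <- 0:2500
  kern <- tk^10.1 * exp(-10.1 * tk / 930)
  kern <- kern / max(kern)
  expected <- 0.5 * mean(kern[701:1201])
  expect_equal(diff_raw, expected, tolerance = 0.1 / expected)
})

test_that("epochs outside the trace or fully missing are excluded with a logged reason", {
  tr <- clean_trace(seed = 7)
  tr$events$time_ms[1] <- 100             # epoch would start before the trace
  pe <- preprocess_pupil(tr, soft_config(pupil_filter = FALSE))
  expect_equal(nrow(pe$exclusions), 1L)
  expect_match(pe$exclusions$reason[1], "outside")
  expect_equal(nrow(pe$data), nrow(tr$events) - 1L)
})

test_that("the printed pupil passband triggers a loud warning", {
  tr <- clean_trace(seed = 8)
  # both the passband sanity warning and the at-Nyquist low-pass skip fire
  expect_warning(
    expect_warning(preprocess_pupil(tr, pipeline_config()), "passband"),
    "Nyquist")
})

test_that("EEG band-limiting attenuates line noise and removes DC offsets", {
  fs <- 512
  t <- seq(0, 6, by = 1 / fs)
  sine60 <- matrix(sin(2 * pi * 60 * t), nrow = 1)
  cfg <- pipeline_config()
  ep <- epoch_eeg(sine60, fs, events_ms = c(2000, 3000), config = cfg)
  rms_out <- sqrt(mean(ep$data^2))
  expect_lt(20 * log10(rms_out / sqrt(0.5)), -20)   # > 20 dB attenuation

  # 60 s recording so the 0.1 Hz high-pass transients die out mid-recording
  t_long <- seq(0, 60, by = 1 / 256)
  dc <- matrix(5, nrow = 2, ncol = length(t_long))
  ep2 <- epoch_eeg(dc, 256, events_ms = 30000, config = cfg)
  expect_lt(max(abs(ep2$data)), 0.05)

  # out-of-range events are dropped and logged, the rest epoched
  ep3 <- epoch_eeg(sine60, fs, events_ms = c(50, 2000, 3000), config = cfg)
  expect_equal(nrow(attr(ep3, "exclusions")), 1L)
  expect_equal(dim(ep3$data)[1], 2L)
  expect_equal(dim(ep3$data)[3], round(0.7 * 256))
})

test_that("ROI averaging matches a naive loop and is label-driven", {
  sched <- generate_schedule(1, 16, seed = 9)
  ds <- simulate_eeg(sched, tuning_config(n_sensors = 64, snr = 0.5), seed = 9,
                     epoch_window_ms = c(-50, 150))
  roi <- c("O1", "Oz", "POz")
  erp <- roi_mean(ds, roi)
  # naive loop oracle
  cells <- cell_labels(sched)
  idx <- match(roi, ds$sensor_labels)
  for (cl in levels(cells)) {
    sel <- which(cells == cl)
    for (t in c(1, 20)) {
      vals <- c()
      for (j in sel) vals <- c(vals, mean(ds$data[j, idx, t]))
      expect_equal(unname(erp[cl, t]), mean(vals), tolerance = 1e-12)
    }
  }
  # single-sensor ROI equals that sensor's trial means; order is irrelevant
  one <- roi_mean(ds, "Oz")
  oz <- match("Oz", ds$sensor_labels)
  expect_equal(unname(one["VEME", ]),
               unname(colMeans(ds$data[cells == "VEME", oz, ])), tolerance = 1e-12)
  expect_equal(roi_mean(ds, rev(roi)), erp)
  expect_error(roi_mean(ds, c("Oz", "XX9")), "XX9")
})

test_that("schedules, behaviour tables and pupil traces round-trip through CSV", {
  dir <- withr::local_tempdir()
  sched <- generate_schedule(2, 16, seed = 10)
  p <- file.path(dir, "sched.csv")
  write_schedule(sched, p)
  back <- read_schedule(p)
  expect_silent(validate_schedule(back))
  expect_equal(back$target_orientation_deg, sched$target_orientation_deg,
               tolerance = 1e-9)
  expect_equal(back$visual_expected, sched$visual_expected)

  beh <- data.frame(subject = 1, trial_index = sched$trial_index,
                    cell = as.character(cell_labels(sched)),
                    target_deg = sched$target_orientation_deg,
                    response_deg = simulate_behavior(sched, seed = 1))
  pb <- file.path(dir, "beh.csv")
  write_behavior(beh, pb)
  expect_equal(read_behavior(pb)$response_deg, as.numeric(beh$response_deg),
               tolerance = 1e-9)
  expect_error(write_behavior(beh[, -3], pb), "cell")

  tr <- clean_trace(seed = 11)
  pt <- file.path(dir, "pupil.csv")
  write_pupil(tr, pt)
  tr2 <- read_pupil(pt)
  expect_equal(tr2$diameter[!tr$missing], tr$diameter[!tr$missing], tolerance = 1e-6)
  expect_equal(tr2$events$time_ms, tr$events$time_ms)
  expect_equal(tr2$sampling_rate_hz, 1000)
})

test_that("epoched datasets round-trip bit-exactly through the text bundle", {
  sched <- generate_schedule(1, 16, seed = 12)
  ds <- simulate_eeg(sched, tuning_config(n_sensors = 5, snr = 1), seed = 12,
                     epoch_window_ms = c(-50, 100))
  dir <- withr::local_tempdir()
  write_epochs(ds, file.path(dir, "ep"))
  back <- read_epochs(file.path(dir, "ep"))
  expect_identical(back$data, ds$data)
  expect_equal(back$sensor_labels, ds$sensor_labels)
  expect_equal(back$schedule$target_orientation_deg,
               ds$schedule$target_orientation_deg, tolerance = 1e-9)
})

test_that("the EyeLink ASC subset reader extracts samples and blink events", {
  lines <- c("** RECORDED BY EyeLink",
             "MSG 1000 start",
             sprintf("%d  512.0  384.0  %1.1f  ...", seq(1000, 1099),
                     c(rep(900, 40), rep(0, 10), rep(905, 50))),
             "SBLINK R 1040",
             "EBLINK R 1040 1049 10")
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(lines, f)
  tr <- read_eyelink_asc(f)
  expect_equal(length(tr$time_ms), 100)
  expect_equal(nrow(tr$blinks), 1)
  expect_equal(sum(tr$missing), 10)
  expect_equal(tr$sampling_rate_hz, 1000)

  bad <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("1000 1.0"), bad)
  expect_error(read_eyelink_asc(bad), "line 1")
})

test_that("configurations round-trip through JSON and runs log their seed", {
  cfg <- pipeline_config(pupil_lowpass_hz = 4, seed = 99L)
  f <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$pupil_lowpass_hz, 4)
  expect_equal(cfg2$seed, 99L)
  expect_equal(cfg2$roi, cfg$roi)
  expect_message(log_run(cfg), "seed 99")
  expect_error(pipeline_config(nope = 1), "unknown config field")
})
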