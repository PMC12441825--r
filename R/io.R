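# Plain-text serialisation: schedules, behaviour tables, pupil traces,
# epoched datasets (text bundle), and a reader for the EyeLink ASC subset
# (SAMPLES plus SBLINK/EBLINK events).

#' Write / read a trial schedule as CSV
#'
#' One row per trial with the exact schedule field names; the round trip
#' preserves all schedule invariants.
#'
#' @param schedule a `trial_schedule`.
#' @param path CSV file path.
#' @return `write_schedule`: the path, invisibly. `read_schedule`: a
#'   `trial_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("trial_schedule", "data.frame")
  validate_schedule(df)
  df
}

#' Write / read a behaviour table as CSV
#'
#' Columns: `subject`, `trial_index`, `cell`, `target_deg`, `response_deg`.
#'
#' @param behavior data frame with the columns above.
#' @param path CSV file path.
#' @return the path / the data frame.
#' @export
write_behavior <- function(behavior, path) {
  req <- c("subject", "trial_index", "cell", "target_deg", "response_deg")
  missing_cols <- setdiff(req, names(behavior))
  if (length(missing_cols)) {
    stop("behavior table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(behavior[, req], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  utils::read.csv(path)
}

#' Write / read a pupil trace as CSV
#'
#' The samples file has columns `time_ms`, `diameter`, `missing`; events go
#' to a companion CSV with `trial_index`, `time_ms`, `cell`.
#'
#' @param trace a `pupil_trace`.
#' @param path samples CSV path.
#' @param events_path events CSV path (default: `path` with `_events`
#'   inserted before the extension).
#' @return the path / a `pupil_trace`.
#' @export
write_pupil <- function(trace, path, events_path = sub("(\\.[^.]+)$", "_events\\1", path)) {
  utils::write.csv(data.frame(time_ms = trace$time_ms,
                              diameter = ifelse(trace$missing, NA, trace$diameter),
                              missing = trace$missing),
                   path, row.names = FALSE)
  utils::write.csv(trace$events, events_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pupil
#' @export
read_pupil <- function(path, events_path = sub("(\\.[^.]+)$", "_events\\1", path)) {
  samples <- utils::read.csv(path)
  events <- utils::read.csv(events_path)
  dt <- diff(samples$time_ms)
  structure(list(time_ms = samples$time_ms, diameter = samples$diameter,
                 missing = as.logical(samples$missing), events = events,
                 sampling_rate_hz = 1000 / stats::median(dt)),
            class = "pupil_trace")
}

# full-precision numeric CSV: every value printed with %.17g so the round
# trip is bit-exact
write_matrix_exact <- function(m, path) {
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, path)
}

read_matrix_exact <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, ","), as.numeric))
}

#' Write / read an epoched dataset as a text bundle
#'
#' Serialises an [epoched_dataset()] to a directory holding `meta.json`
#' (dimensions, rate, window, sensor labels), `schedule.csv` and
#' `data_trialNNN.csv` matrices (sensors x timepoints, full precision: the
#' data tensor round-trips bit-exactly).
#'
#' @param dataset an [epoched_dataset()].
#' @param dir directory path (created if needed).
#' @return the directory / an `epoched_dataset`.
#' @export
write_epochs <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(dataset$data)
  meta <- list(n_trials = d[1], n_sensors = d[2], n_timepoints = d[3],
               sampling_rate_hz = dataset$sampling_rate_hz,
               epoch_window_ms = dataset$epoch_window_ms,
               sensor_labels = dataset$sensor_labels)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "meta.json"))
  if (!is.null(dataset$schedule)) {
    write_schedule(dataset$schedule, file.path(dir, "schedule.csv"))
  }
  for (j in seq_len(d[1])) {
    write_matrix_exact(dataset$data[j, , , drop = TRUE],
                       file.path(dir, sprintf("data_trial%04d.csv", j)))
  }
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  data <- array(0, c(meta$n_trials, meta$n_sensors, meta$n_timepoints))
  for (j in seq_len(meta$n_trials)) {
    data[j, , ] <- read_matrix_exact(file.path(dir, sprintf("data_trial%04d.csv", j)))
  }
  sched_path <- file.path(dir, "schedule.csv")
  schedule <- if (file.exists(sched_path)) read_schedule(sched_path) else NULL
  epoched_dataset(data, meta$sampling_rate_hz, meta$epoch_window_ms,
                  sensor_labels = meta$sensor_labels, schedule = schedule)
}

#' Read the sample/blink subset of an EyeLink ASC file
#'
#' Parses monocular sample lines (`timestamp x y pupil ...`) and
#' `SBLINK`/`EBLINK` event lines. Samples falling inside blink intervals, or
#' with zero/missing pupil size, are flagged missing.
#'
#' @param path ASC file path.
#' @return a `pupil_trace`: `time_ms`, `diameter`, `missing`, `blinks`
#'   (data frame `onset_ms`, `offset_ms`), `sampling_rate_hz`, and an empty
#'   `events` table (experiment events are not encoded in ASC samples).
#' @export
read_eyelink_asc <- function(path) {
  lines <- readLines(path)
  ts <- numeric(0); pup <- numeric(0)
  blink_on <- numeric(0); blink_off <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "**")) next
    fields <- strsplit(ln, "[ \t]+")[[1]]
    if (grepl("^[0-9]", fields[1])) {
      if (length(fields) < 4) {
        stop(sprintf("malformed sample at line %d: expected >= 4 fields, got %d.",
                     i, length(fields)), call. = FALSE)
      }
      ts <- c(ts, as.numeric(fields[1]))
      p <- suppressWarnings(as.numeric(fields[4]))
      pup <- c(pup, if (is.na(p)) 0 else p)
    } else if (fields[1] == "EBLINK") {
      if (length(fields) < 4) {
        stop(sprintf("malformed EBLINK at line %d.", i), call. = FALSE)
      }
      blink_on <- c(blink_on, as.numeric(fields[3]))
      blink_off <- c(blink_off, as.numeric(fields[4]))
    }
    # SBLINK lines carry no extra information beyond the EBLINK summary
  }
  if (!length(ts)) stop("no samples found in ASC file.", call. = FALSE)
  t0 <- ts[1]
  time_ms <- ts - t0
  missing <- pup <= 0
  for (b in seq_along(blink_on)) {
    missing <- missing | (ts >= blink_on[b] & ts <= blink_off[b])
  }
  rate <- 1000 / stats::median(diff(time_ms))
  structure(list(time_ms = time_ms,
                 diameter = ifelse(missing, NA_real_, pup),
                 missing = missing,
                 events = data.frame(trial_index = integer(0),
                                     time_ms = numeric(0), cell = character(0)),
                 blinks = data.frame(onset_ms = blink_on - t0,
                                     offset_ms = blink_off - t0),
                 sampling_rate_hz = rate),
            class = "pupil_trace")
}
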