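# Counterbalanced 2x2 probabilistic-cueing trial schedules.
#
# The design crosses visual expectancy (cue orientation matches the target
# vs. differs by more than 30 degrees) with motor expectancy (target appears
# immediately on button release vs. after an extra delay). Both cues are
# valid with probability 0.75 by default and the two factors are
# counterbalanced, so the four cells occupy exact shares 9:3:3:1.

CELL_LEVELS <- c("VEME", "VEMU", "VUME", "VUMU")

#' Cell label of each trial
#'
#' Combines the visual and motor expectancy flags into one of the four
#' condition labels `VEME`, `VEMU`, `VUME`, `VUMU` (visual/motor
#' expected/unexpected).
#'
#' @param schedule a `trial_schedule` (or any data frame with logical
#'   `visual_expected` and `motor_expected` columns).
#' @return factor with levels `VEME`, `VEMU`, `VUME`, `VUMU`.
#' @export
cell_labels <- function(schedule) {
  factor(paste0(ifelse(schedule$visual_expected, "VE", "VU"),
                ifelse(schedule$motor_expected, "ME", "MU")),
         levels = CELL_LEVELS)
}

#' Generate a counterbalanced probabilistic-cueing trial schedule
#'
#' Builds the full 2x2 expectancy design: every trial has a visual cue
#' orientation, a target orientation, a visual-to-motor-cue delay drawn
#' uniformly from `delay_range_ms`, and (on motor-unexpected trials only) an
#' extra delay between button release and target onset drawn uniformly from
#' one third of the delay-range width. Cell counts are balanced exactly at
#' the experiment level: with 75%/75% validity the four cells occupy exactly
#' 9/16, 3/16, 3/16 and 1/16 of all trials, and condition labels are
#' pseudo-randomly interleaved across blocks.
#'
#' Visual-expected trials have `cue_orientation_deg == target_orientation_deg`;
#' visual-unexpected cues differ from the target by an orientation distance
#' drawn uniformly from (30, 90] degrees, on a random side.
#'
#' @param n_blocks number of blocks (default 10).
#' @param trials_per_block trials per block (default 72).
#' @param visual_validity probability that the visual cue matches the target,
#'   in (0, 1] (default 0.75).
#' @param motor_validity probability that the target appears immediately on
#'   button release, in (0, 1] (default 0.75).
#' @param delay_range_ms length-2 numeric, the support of the uniform
#'   visual-to-motor-cue delay in ms (default `c(250, 1500)`).
#' @param seed integer seed; identical arguments and seed give identical
#'   schedules.
#' @return a `trial_schedule`: a data frame with columns `trial_index`,
#'   `block`, `visual_expected`, `motor_expected`, `target_orientation_deg`,
#'   `cue_orientation_deg`, `cue_to_motor_delay_ms`, `extra_target_delay_ms`
#'   and `seed`.
#' @examples
#' sched <- generate_schedule(seed = 1)
#' table(cell_labels(sched)) / nrow(sched)
#' @export
generate_schedule <- function(n_blocks = 10, trials_per_block = 72,
                              visual_validity = 0.75, motor_validity = 0.75,
                              delay_range_ms = c(250, 1500), seed = 1L) {
  check_scalar(n_blocks, "n_blocks", function(x) is.numeric(x) && x >= 1 && x == round(x), "a positive integer")
  check_scalar(trials_per_block, "trials_per_block", function(x) is.numeric(x) && x >= 1 && x == round(x), "a positive integer")
  for (v in c(visual_validity = visual_validity, motor_validity = motor_validity)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1) {
      stop("validities must lie in (0, 1].", call. = FALSE)
    }
  }
  if (length(delay_range_ms) != 2L || !is.numeric(delay_range_ms) ||
      delay_range_ms[2] < delay_range_ms[1]) {
    stop("`delay_range_ms` must be a non-empty interval c(min, max).", call. = FALSE)
  }

  n_total <- n_blocks * trials_per_block
  p_cell <- c(visual_validity * motor_validity,
              visual_validity * (1 - motor_validity),
              (1 - visual_validity) * motor_validity,
              (1 - visual_validity) * (1 - motor_validity))
  counts <- n_total * p_cell
  if (any(abs(counts - round(counts)) > 1e-9)) {
    denoms <- vapply(p_cell[p_cell > 0], rational_denominator, numeric(1))
    need <- Reduce(lcm2, denoms)
    stop(sprintf(paste0("exact-count balancing impossible: %d trials cannot be split ",
                        "into the requested cell proportions; the total must be a ",
                        "multiple of %d."), n_total, as.integer(need)), call. = FALSE)
  }
  counts <- as.integer(round(counts))

  with_seed(seed, {
    cells <- rep(CELL_LEVELS, times = counts)
    cells <- sample(cells)                       # pseudo-random interleaving
    visual_expected <- substr(cells, 1, 2) == "VE"
    motor_expected <- substr(cells, 3, 4) == "ME"

    target <- stats::runif(n_total, 0, 180)
    cue <- target
    vu <- !visual_expected
    if (any(vu)) {
      offset <- stats::runif(sum(vu), 30, 90)    # distance in (30, 90]
      side <- sample(c(-1, 1), sum(vu), replace = TRUE)
      cue[vu] <- wrap_orientation(target[vu] + side * offset)
    }

    delay <- stats::runif(n_total, delay_range_ms[1], delay_range_ms[2])
    extra <- numeric(n_total)
    mu <- !motor_expected
    if (any(mu)) {
      extra[mu] <- sample_mu_delay(delay_range_ms, n = sum(mu))
    }

    sched <- data.frame(
      trial_index = seq_len(n_total),
      block = rep(seq_len(n_blocks), each = trials_per_block),
      visual_expected = visual_expected,
      motor_expected = motor_expected,
      target_orientation_deg = target,
      cue_orientation_deg = cue,
      cue_to_motor_delay_ms = delay,
      extra_target_delay_ms = extra,
      seed = as.integer(seed)
    )
    class(sched) <- c("trial_schedule", "data.frame")
    attr(sched, "delay_range_ms") <- delay_range_ms
    validate_schedule(sched)
    sched
  })
}

#' Draw extra target delays for motor-unexpected trials
#'
#' On motor-unexpected trials the target appears after an additional delay
#' drawn uniformly from one third of the visual-to-motor-cue delay range:
#' the support is `(0, width/3]` ms, so the delay is always strictly
#' positive. For the default range `[250, 1500]` the support is
#' (0, 416.67] ms with mean 208.33 ms.
#'
#' @param delay_range_ms length-2 numeric interval in ms with positive width.
#' @param n number of draws.
#' @return numeric vector of delays in ms.
#' @export
sample_mu_delay <- function(delay_range_ms, n = 1) {
  width <- delay_range_ms[2] - delay_range_ms[1]
  if (!is.finite(width) || width <= 0) {
    stop("`delay_range_ms` must have positive width.", call. = FALSE)
  }
  # runif draws in the open interval, so values are strictly positive and
  # never exceed width/3
  width / 3 - stats::runif(n, 0, width / 3)
}

#' Validate trial-schedule invariants
#'
#' Checks the structural invariants of a schedule: visual-expected cues equal
#' their targets, visual-unexpected cues differ by more than 30 degrees,
#' extra target delays are zero exactly on motor-expected trials, and all
#' visual-to-motor delays lie inside the design range.
#'
#' @param schedule a `trial_schedule`.
#' @return the schedule, invisibly; errors on violation.
#' @export
validate_schedule <- function(schedule) {
  req <- c("trial_index", "block", "visual_expected", "motor_expected",
           "target_orientation_deg", "cue_orientation_deg",
           "cue_to_motor_delay_ms", "extra_target_delay_ms")
  missing_cols <- setdiff(req, names(schedule))
  if (length(missing_cols)) {
    stop("schedule is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ve <- schedule$visual_expected
  d <- orientation_dist(schedule$cue_orientation_deg,
                        schedule$target_orientation_deg)
  if (any(d[ve] > 1e-9)) {
    stop("visual-expected trials must have cue equal to target.", call. = FALSE)
  }
  if (any(d[!ve] <= 30)) {
    stop("visual-unexpected cues must differ from the target by more than 30 degrees.",
         call. = FALSE)
  }
  me <- schedule$motor_expected
  if (any(schedule$extra_target_delay_ms[me] != 0) ||
      any(schedule$extra_target_delay_ms[!me] <= 0)) {
    stop("extra target delay must be 0 iff the trial is motor-expected.",
         call. = FALSE)
  }
  rng <- attr(schedule, "delay_range_ms")
  if (!is.null(rng)) {
    if (any(schedule$cue_to_motor_delay_ms < rng[1] - 1e-9) ||
        any(schedule$cue_to_motor_delay_ms > rng[2] + 1e-9)) {
      stop("cue_to_motor_delay_ms outside the design range.", call. = FALSE)
    }
  }
  invisible(schedule)
}

#' Equate trial counts across the four cells (confound matching)
#'
#' Subsamples the over-represented cells down to the size of the smallest
#' cell by discarding, within each cell, the trials with the longest
#' visual-to-motor-cue delays (ties broken by trial index). For the default
#' 720-trial 75%/75% design this retains exactly 45 trials per cell. The
#' original trial order is preserved and the operation is idempotent.
#'
#' @param schedule a `trial_schedule`.
#' @return the matched subset, a `trial_schedule`.
#' @export
match_trials <- function(schedule) {
  validate_schedule(schedule)
  cells <- cell_labels(schedule)
  counts <- table(cells)
  if (any(counts == 0)) {
    stop("cannot match trials: cell(s) ",
         paste(names(counts)[counts == 0], collapse = ", "), " are empty.",
         call. = FALSE)
  }
  n_keep <- min(counts)
  keep <- logical(nrow(schedule))
  for (cl in CELL_LEVELS) {
    idx <- which(cells == cl)
    ord <- idx[order(schedule$cue_to_motor_delay_ms[idx],
                     schedule$trial_index[idx])]
    keep[ord[seq_len(n_keep)]] <- TRUE
  }
  out <- schedule[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(schedule)
  attr(out, "delay_range_ms") <- attr(schedule, "delay_range_ms")
  out
}

#' @export
print.trial_schedule <- function(x, ...) {
  counts <- table(cell_labels(x))
  cat(sprintf("Trial schedule: %d trials in %d block(s)\n",
              nrow(x), length(unique(x$block))))
  cat("  cells:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  if (!is.null(x$seed)) cat("  seed:", x$seed[1], "\n")
  invisible(x)
}
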