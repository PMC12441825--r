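# Synthetic continuous-reproduction behaviour.
#
# Responses follow the same mixture the fitting routine assumes: with
# probability g (per condition cell) the response is a uniform guess on the
# orientation circle, otherwise it is the target plus a von Mises error on
# the doubled-angle circle with concentration kappa.

#' Ground-truth behavioural mixture parameters per condition cell
#'
#' @param kappa_per_cell concentration of the von Mises error component
#'   (doubled-angle radians), length 4 in cell order `VEME, VEMU, VUME, VUMU`
#'   or length 1 (recycled).
#' @param guess_rate_per_cell probability of a uniform guess per cell, in
#'   `[0, 1]`; length 4 or 1.
#' @return a `behavior_truth`.
#' @export
behavior_truth <- function(kappa_per_cell = 8, guess_rate_per_cell = 0.25) {
  kappa <- rep_len(kappa_per_cell, 4L)
  guess <- rep_len(guess_rate_per_cell, 4L)
  if (any(kappa < 0)) stop("kappa must be non-negative.", call. = FALSE)
  if (any(guess < 0 | guess > 1)) stop("guess rates must lie in [0, 1].", call. = FALSE)
  names(kappa) <- names(guess) <- CELL_LEVELS
  structure(list(kappa_per_cell = kappa, guess_rate_per_cell = guess),
            class = "behavior_truth")
}

#' Simulate orientation-reproduction responses
#'
#' For each trial, with probability `g_cell` the response is drawn uniformly
#' from `[0, 180)`; otherwise it equals the target orientation plus an error
#' `e` whose doubled angle `2e` (radians) is von Mises distributed with mean
#' 0 and concentration `kappa_cell`.
#'
#' @param schedule a `trial_schedule`.
#' @param truth a [behavior_truth()].
#' @param seed integer seed.
#' @return numeric vector of responses in `[0, 180)` degrees, with the
#'   per-trial guess indicator attached as attribute `is_guess`.
#' @export
simulate_behavior <- function(schedule, truth = behavior_truth(), seed = 1L) {
  stopifnot(inherits(truth, "behavior_truth"))
  cells <- cell_labels(schedule)
  n <- nrow(schedule)
  with_seed(seed, {
    g <- truth$guess_rate_per_cell[as.integer(cells)]
    kap <- truth$kappa_per_cell[as.integer(cells)]
    is_guess <- stats::runif(n) < g
    resp <- numeric(n)
    resp[is_guess] <- stats::runif(sum(is_guess), 0, 180)
    if (any(!is_guess)) {
      idx <- which(!is_guess)
      # group by kappa so the rejection sampler runs once per distinct value
      for (kv in unique(kap[idx])) {
        sel <- idx[kap[idx] == kv]
        err_deg <- rvonmises(length(sel), kv) * 90 / pi   # halve the doubled angle
        resp[sel] <- wrap_orientation(schedule$target_orientation_deg[sel] + err_deg)
      }
    }
    structure(resp, is_guess = is_guess)
  })
}
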