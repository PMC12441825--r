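# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global RNG state so that seeded generators are pure
#' functions of their arguments and do not disturb the caller's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number.", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Wrap angles into the orientation space [0, 180)
#' @param theta_deg numeric vector of angles in degrees.
#' @return angles wrapped into `[0, 180)`.
#' @keywords internal
wrap_orientation <- function(theta_deg) {
  out <- theta_deg %% 180
  out[out < 0] <- out[out < 0] + 180
  out
}

#' Signed orientation difference in (-90, 90]
#'
#' Difference `a - b` on the 180-degree orientation circle, mapped to the
#' half-open interval `(-90, 90]`.
#' @param a_deg,b_deg angle vectors in degrees.
#' @return signed differences in degrees.
#' @keywords internal
orientation_diff <- function(a_deg, b_deg) {
  d <- (a_deg - b_deg) %% 180
  d[d > 90] <- d[d > 90] - 180
  # map the boundary -90 to +90 so the interval is half-open at -90
  d[d == -90] <- 90
  d
}

#' Absolute circular distance between orientations (degrees, 0..90)
#' @keywords internal
orientation_dist <- function(a_deg, b_deg) {
  abs(orientation_diff(a_deg, b_deg))
}

# log von Mises density at x (radians) with mean 0 and concentration kappa,
# stable for large kappa via the exponentially scaled Bessel function.
dvonmises_log <- function(x, kappa) {
  if (kappa < 0) stop("kappa must be non-negative.", call. = FALSE)
  # log I0(kappa) = log(besselI(kappa, 0, TRUE)) + kappa
  kappa * cos(x) - log(2 * pi) - (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
}

# Draw n samples from a von Mises(0, kappa) distribution (radians in (-pi, pi]).
# Best & Fisher (1979) rejection sampler; kappa = 0 falls back to uniform.
rvonmises <- function(n, kappa) {
  if (kappa < 1e-9) {
    return(stats::runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    nk <- sum(keep)
    if (nk > 0) {
      u3 <- stats::runif(nk)
      theta <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f[keep])))
      out[(got + 1L):(got + nk)] <- theta
      got <- got + nk
    }
  }
  out
}

# Mean resultant length of angles given in radians on the full circle.
resultant_length <- function(theta_rad) {
  Mod(mean(exp(1i * theta_rad)))
}

# Smallest positive integer q such that q * p is (numerically) an integer,
# searching q = 1..max_q. Used for exact-count balancing of cell proportions.
rational_denominator <- function(p, max_q = 10000L, tol = 1e-9) {
  for (q in seq_len(max_q)) {
    if (abs(q * p - round(q * p)) < tol) {
      return(q)
    }
  }
  stop("proportion has no small rational representation", call. = FALSE)
}

lcm2 <- function(a, b) {
  gcd <- function(x, y) if (y == 0) x else gcd(y, x %% y)
  a / gcd(a, b) * b
}

# Assert that x is a single logical/numeric of the given predicate; small
# argument-checking helper used by user-facing constructors.
check_scalar <- function(x, name, predicate, what) {
  if (length(x) != 1L || !predicate(x)) {
    stop(sprintf("`%s` must be %s.", name, what), call. = FALSE)
  }
  invisible(TRUE)
}
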