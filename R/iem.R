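# Inverted encoding model for orientation decoding from multichannel epochs.
#
# A forward model B = W C + E maps five hypothetical orientation channels
# (half-wave-rectified cosines raised to the fourth power, preferences every
# 36 degrees) to sensor space. Sensor weights are estimated per channel by
# least squares; noise-covariance-aware spatial filters (with analytic
# shrinkage regularisation of the residual covariance) invert the model, and
# reconstructed channel responses are converted to a decoded orientation via
# the doubled-angle population vector.

#' Orientation channel basis set
#'
#' Five hypothetical orientation channels with preferred orientations linearly
#' spaced over the 180-degree orientation space (0, 36, 72, 108, 144 degrees;
#' the 180-degree endpoint is the alias of 0 and is excluded). Each channel's
#' tuning curve is a half-wave-rectified cosine raised to the `exponent`
#' power, zero for orientation distances of 45 degrees or more.
#'
#' @param n_channels number of channels (default 5).
#' @param exponent power applied to the rectified cosine (default 4).
#' @return an `iem_basis` object with fields `preferred_deg` and `exponent`.
#' @export
iem_basis <- function(n_channels = 5, exponent = 4) {
  check_scalar(n_channels, "n_channels", function(x) is.numeric(x) && x >= 2 && x == round(x), "an integer >= 2")
  structure(list(preferred_deg = 180 * (seq_len(n_channels) - 1) / n_channels,
                 exponent = exponent),
            class = "iem_basis")
}

#' Idealised channel responses to a set of orientations
#'
#' Evaluates each channel's tuning curve
#' `max(0, cos(pi * (theta - phi) / 90))^exponent` at the given orientations,
#' producing the design matrix `C` (channels x presentations) of the forward
#' model.
#'
#' @param orientations_deg orientations in `[0, 180)` degrees.
#' @param basis an [iem_basis()].
#' @return matrix of channel responses, `n_channels` x `length(orientations_deg)`,
#'   entries in `[0, 1]`.
#' @export
channel_responses <- function(orientations_deg, basis = iem_basis()) {
  stopifnot(inherits(basis, "iem_basis"))
  theta <- wrap_orientation(orientations_deg)
  resp <- outer(basis$preferred_deg, theta,
                function(phi, th) pmax(0, cos(pi * (th - phi) / 90))^basis$exponent)
  dimnames(resp) <- list(paste0("ch", basis$preferred_deg), NULL)
  resp
}

#' Centre a data matrix across presentations
#'
#' Removes the mean across presentations (columns) from each row, the
#' normalisation applied to both `B` (sensors x presentations) and `C`
#' (channels x presentations) before model fitting.
#'
#' @param x numeric matrix, rows = sensors or channels, columns = presentations.
#' @return centred matrix with zero row means.
#' @export
center_presentations <- function(x) {
  x - rowMeans(x)
}

#' Least-squares forward weights, one channel at a time
#'
#' Estimates the sensor weight vector of each channel independently by
#' one-regressor least squares, `w_i = B c_i' / (c_i c_i')`, exactly as the
#' forward model is written. Inputs are expected to be centred across
#' presentations.
#'
#' @param b_train centred data, sensors x presentations.
#' @param c_train centred channel responses, channels x presentations.
#' @return weight matrix `W`, sensors x channels.
#' @export
fit_forward <- function(b_train, c_train) {
  if (ncol(b_train) != ncol(c_train)) {
    stop("b_train and c_train must have the same number of presentations.", call. = FALSE)
  }
  n_ch <- nrow(c_train)
  W <- matrix(0, nrow(b_train), n_ch)
  for (i in seq_len(n_ch)) {
    ci <- c_train[i, ]
    den <- sum(ci^2)
    if (den < .Machine$double.eps * length(ci)) {
      stop(sprintf("channel %d has zero-variance response vector; cannot fit weights.", i),
           call. = FALSE)
    }
    W[, i] <- (b_train %*% ci) / den
  }
  W
}

# Analytic (Ledoit-Wolf-type) shrinkage of a residual covariance toward the
# scaled identity nu * I, with nu the mean diagonal of the sample covariance.
# Returns the shrinkage intensity in [0, 1].
analytic_shrinkage_intensity <- function(eps) {
  n <- ncol(eps)
  p <- nrow(eps)
  s_n <- tcrossprod(eps) / n
  nu <- mean(diag(s_n))
  d2 <- sum((s_n - diag(nu, p))^2)
  if (d2 < .Machine$double.eps) {
    return(1)
  }
  # mean squared Frobenius distance of per-presentation outer products from S:
  # sum_k ||x_k x_k' - S||^2 = sum_k (x_k'x_k)^2 - n ||S||^2
  b2 <- (sum(colSums(eps^2)^2) - n * sum(s_n^2)) / n^2
  max(0, min(1, b2 / d2))
}

#' Residual noise model with analytic shrinkage
#'
#' Forms per-channel residuals `eps_i = B_train - w_i c_i`, their sample
#' covariance `Sigma_hat = eps eps' / (n_train - 1)`, and the regularised
#' covariance `Sigma_tilde = (1 - lambda) Sigma_hat + lambda nu I`, where
#' `nu` is the mean diagonal of `Sigma_hat` and `lambda` is the analytically
#' determined optimal (Ledoit-Wolf-type) shrinkage intensity. When the
#' residuals vanish entirely (noiseless training data) the model degenerates
#' to the identity covariance so that downstream filters remain defined.
#'
#' @param b_train centred training data, sensors x presentations.
#' @param w_i sensor weight vector of channel `i`.
#' @param c_i centred response vector of channel `i` (length = presentations).
#' @param shrinkage `"analytic"` (default) for the analytic optimal intensity,
#'   `"none"` for no shrinkage, or a number in `[0, 1]`.
#' @return a `channel_noise_model`: list with `residuals`, `raw_cov`,
#'   `shrunk_cov`, `shrinkage`, `nu`, and a `degenerate` flag.
#' @export
estimate_noise <- function(b_train, w_i, c_i, shrinkage = "analytic") {
  n_train <- ncol(b_train)
  if (n_train < 2) {
    stop("at least 2 training presentations are required to estimate noise covariance.",
         call. = FALSE)
  }
  eps <- b_train - tcrossprod(w_i, c_i)
  p <- nrow(b_train)
  raw <- tcrossprod(eps) / (n_train - 1)
  nu <- mean(diag(raw))
  degenerate <- nu < .Machine$double.eps
  if (degenerate) {
    # zero residuals: fall back to the identity-covariance case
    lambda <- 1
    shrunk <- diag(1, p)
  } else {
    lambda <- if (identical(shrinkage, "analytic")) {
      analytic_shrinkage_intensity(eps)
    } else if (identical(shrinkage, "none")) {
      0
    } else if (is.numeric(shrinkage) && length(shrinkage) == 1L &&
               shrinkage >= 0 && shrinkage <= 1) {
      shrinkage
    } else {
      stop("`shrinkage` must be \"analytic\", \"none\", or a number in [0, 1].",
           call. = FALSE)
    }
    shrunk <- (1 - lambda) * raw + diag(lambda * nu, p)
  }
  structure(list(residuals = eps, raw_cov = raw, shrunk_cov = shrunk,
                 shrinkage = lambda, nu = nu, degenerate = degenerate),
            class = "channel_noise_model")
}

#' Noise-covariance-aware spatial filter for one channel
#'
#' Computes `v_i = Sigma^{-1} w_i / (w_i' Sigma^{-1} w_i)`, the minimum-noise
#' unit-gain filter for channel `i`: it satisfies `v_i' w_i = 1` while
#' suppressing directions of high residual covariance (correlated noise on
#' neighbouring sensors). With identity covariance it reduces to
#' `w / (w'w)`.
#'
#' @param w_i sensor weight vector.
#' @param sigma symmetric positive-definite (shrunk) covariance, or a
#'   `channel_noise_model`.
#' @return filter vector `v_i` with `sum(v_i * w_i) == 1`.
#' @export
spatial_filter <- function(w_i, sigma) {
  if (inherits(sigma, "channel_noise_model")) sigma <- sigma$shrunk_cov
  if (sum(abs(w_i)) == 0) stop("weight vector is zero.", call. = FALSE)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop("covariance is not symmetric positive definite; cannot form filter.",
         call. = FALSE)
  }
  sol <- backsolve(ch, forwardsolve(t(ch), w_i))
  den <- sum(w_i * sol)
  as.numeric(sol) / den
}

#' Reconstruct channel responses in a test set
#'
#' Applies the filter matrix to held-out data: `C_test = V' B_test`.
#'
#' @param v_filters filter matrix `V`, sensors x channels.
#' @param b_test centred test data, sensors x presentations.
#' @return reconstructed channel responses, channels x presentations.
#' @export
reconstruct <- function(v_filters, b_test) {
  crossprod(v_filters, b_test)
}

#' Decode orientation from reconstructed channel responses
#'
#' Treats the channel responses as weights on phasors at the doubled
#' preferred angles, `z = sum_k c_k exp(2i phi_k)`, and returns
#' `arg(z) / 2` mapped to `[0, 180)`. Doubling maps the 180-degree
#' orientation space onto the full circle. If the phasors cancel (|z| below
#' `tol` relative to `sum |c_k|`) the decode is undefined and `NA` is
#' returned.
#'
#' @param c_hat matrix of channel responses (channels x presentations) or a
#'   single response vector.
#' @param basis the [iem_basis()] whose preferred angles built `c_hat`.
#' @param tol relative magnitude below which the decode is flagged undefined.
#' @return decoded orientations in degrees, `NA` where undefined.
#' @export
decode_orientation <- function(c_hat, basis = iem_basis(), tol = 1e-12) {
  if (is.null(dim(c_hat))) c_hat <- matrix(c_hat, ncol = 1)
  phasor <- exp(2i * basis$preferred_deg * pi / 180)
  z <- as.vector(phasor %*% c_hat)
  scale <- colSums(abs(c_hat))
  out <- (Arg(z) * 90 / pi) %% 180
  out[Mod(z) <= tol * pmax(scale, .Machine$double.xmin)] <- NA_real_
  out
}

#' Circular decoding accuracy
#'
#' Projects the decoded-minus-presented orientation differences onto the zero
#' direction: `r = Re[(1/n) sum_j exp(i * 2 * (theta_hat_j - theta_j))]` with
#' angles doubled to map orientations onto the full circle (set
#' `double_angle = FALSE` for the raw-angle variant). Perfect decoding gives
#' 1, a constant 90-degree error gives -1, and unrelated decodes give values
#' near 0. Undefined (`NA`) decodes are excluded; their count is attached as
#' attribute `n_undefined`.
#'
#' @param decoded_deg decoded orientations (degrees, `NA` = undefined).
#' @param presented_deg presented orientations (degrees).
#' @param double_angle logical; double the angular differences (default TRUE).
#' @return accuracy scalar in `[-1, 1]` with attributes `n` and `n_undefined`.
#' @export
decoding_accuracy <- function(decoded_deg, presented_deg, double_angle = TRUE) {
  if (length(decoded_deg) != length(presented_deg)) {
    stop("decoded and presented orientation vectors must have equal length.",
         call. = FALSE)
  }
  ok <- !is.na(decoded_deg) & !is.na(presented_deg)
  n_undef <- sum(!ok)
  if (!any(ok)) stop("no defined decodes; accuracy is undefined.", call. = FALSE)
  k <- if (double_angle) 2 else 1
  diff_rad <- k * (decoded_deg[ok] - presented_deg[ok]) * pi / 180
  r <- Re(mean(exp(1i * diff_rad)))
  structure(r, n = sum(ok), n_undefined = n_undef)
}

#' Cross-validated per-timepoint orientation decoding
#'
#' Runs the full inverted-encoding pipeline independently at every timepoint
#' with k-fold cross-validation over trials: on each training fold the data
#' and design are centred across presentations, forward weights fitted,
#' per-channel residual covariances shrunk and inverted into spatial filters;
#' the held-out fold is centred, reconstructed and decoded, and the test-fold
#' decodes are concatenated. Accuracy is reported per timepoint overall and
#' within each 2x2 condition cell.
#'
#' @param dataset an [epoched_dataset()] (or a list with `data`
#'   (trials x sensors x timepoints) and `schedule`).
#' @param k number of cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param basis the [iem_basis()].
#' @param shrinkage passed to [estimate_noise()].
#' @param double_angle passed to [decoding_accuracy()].
#' @param orientations optional per-trial orientations (degrees); defaults to
#'   `schedule$target_orientation_deg`.
#' @return a `decode_result`: list with `decoded_deg` (trials x timepoints),
#'   `channel_responses` (trials x channels x timepoints), `accuracy`
#'   (timepoints x cells data frame incl. the overall column), `resultant`
#'   (mean resultant length per timepoint), `folds`, `n_undefined`, `seed`.
#' @export
crossvalidated_decode <- function(dataset, k = 10, seed = 1L,
                                  basis = iem_basis(), shrinkage = "analytic",
                                  double_angle = TRUE, orientations = NULL) {
  data <- dataset$data
  stopifnot(length(dim(data)) == 3L)
  n_trials <- dim(data)[1]
  n_time <- dim(data)[3]
  if (n_trials < k) {
    stop(sprintf("need at least k = %d trials for %d-fold cross-validation.", k, k),
         call. = FALSE)
  }
  if (is.null(orientations)) {
    orientations <- dataset$schedule$target_orientation_deg
  }
  stopifnot(length(orientations) == n_trials)

  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n_trials)))
  c_full <- channel_responses(orientations, basis)
  n_ch <- nrow(c_full)

  decoded <- matrix(NA_real_, n_trials, n_time)
  chan <- array(NA_real_, c(n_trials, n_ch, n_time))
  for (t in seq_len(n_time)) {
    b_t <- t(data[, , t])                    # sensors x trials
    for (f in seq_len(k)) {
      test <- folds == f
      b_tr <- center_presentations(b_t[, !test, drop = FALSE])
      c_tr <- center_presentations(c_full[, !test, drop = FALSE])
      W <- fit_forward(b_tr, c_tr)
      V <- matrix(0, nrow(b_tr), n_ch)
      for (i in seq_len(n_ch)) {
        nm <- estimate_noise(b_tr, W[, i], c_tr[i, ], shrinkage = shrinkage)
        V[, i] <- spatial_filter(W[, i], nm)
      }
      # centre the held-out fold with the training-fold sensor means so the
      # test transform never peeks at test statistics
      b_te <- b_t[, test, drop = FALSE] - rowMeans(b_t[, !test, drop = FALSE])
      c_te <- reconstruct(V, b_te)
      chan[test, , t] <- t(c_te)
      decoded[test, t] <- decode_orientation(c_te, basis)
    }
  }

  cells <- if (!is.null(dataset$schedule)) cell_labels(dataset$schedule) else NULL
  acc <- data.frame(timepoint = seq_len(n_time),
                    overall = NA_real_, resultant = NA_real_)
  if (!is.null(cells)) for (cl in CELL_LEVELS) acc[[cl]] <- NA_real_
  n_undef <- 0L
  for (t in seq_len(n_time)) {
    ok <- !is.na(decoded[, t])
    n_undef <- n_undef + sum(!ok)
    if (any(ok)) {
      a <- decoding_accuracy(decoded[ok, t], orientations[ok], double_angle)
      acc$overall[t] <- as.numeric(a)
      kk <- if (double_angle) 2 else 1
      acc$resultant[t] <- resultant_length(kk * (decoded[ok, t] - orientations[ok]) * pi / 180)
      if (!is.null(cells)) {
        for (cl in CELL_LEVELS) {
          sel <- ok & cells == cl
          if (any(sel)) {
            acc[[cl]][t] <- as.numeric(
              decoding_accuracy(decoded[sel, t], orientations[sel], double_angle))
          }
        }
      }
    }
  }
  structure(list(decoded_deg = decoded, channel_responses = chan,
                 accuracy = acc, folds = folds, n_undefined = n_undef,
                 seed = seed, double_angle = double_angle),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("IEM decode result: %d trials x %d timepoints (%d-fold CV)\n",
              nrow(x$decoded_deg), ncol(x$decoded_deg), max(x$folds)))
  cat(sprintf("  peak accuracy %.3f at timepoint %d; undefined decodes: %d\n",
              max(x$accuracy$overall, na.rm = TRUE),
              which.max(x$accuracy$overall), x$n_undefined))
  invisible(x)
}
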