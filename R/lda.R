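# Time-resolved linear discriminant analysis of trial expectancy.
#
# Binary LDA with shrinkage-regularised pooled covariance, used per
# timepoint on all sensor amplitudes. Because the design is 75/25
# imbalanced, the majority class is repeatedly subsampled to the minority
# count before cross-validation so that chance is a well-defined 50%.

#' Fit a binary shrinkage LDA classifier
#'
#' Weight vector `w = Sigma_pooled^{-1} (mu_1 - mu_0)` with the pooled
#' within-class covariance regularised by analytic (Ledoit-Wolf-type)
#' shrinkage toward the scaled identity; the decision threshold sits at the
#' midpoint of the projected class means.
#'
#' @param x trials x features matrix.
#' @param y binary labels (logical, or any two-level vector).
#' @param shrinkage `"analytic"` (default), `"none"`, or a number in `[0, 1]`.
#' @return an `lda_model` with `weights`, `threshold`, `means`, `levels`,
#'   `shrinkage`.
#' @export
fit_lda <- function(x, y, shrinkage = "analytic") {
  x <- as.matrix(x)
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("exactly two classes are required.", call. = FALSE)
  i0 <- y == lev[1]
  n0 <- sum(i0); n1 <- sum(!i0)
  if (n0 < 2 || n1 < 2) stop("each class needs at least 2 trials.", call. = FALSE)
  mu0 <- colMeans(x[i0, , drop = FALSE])
  mu1 <- colMeans(x[!i0, , drop = FALSE])
  xc <- x
  xc[i0, ] <- sweep(x[i0, , drop = FALSE], 2, mu0)
  xc[!i0, ] <- sweep(x[!i0, , drop = FALSE], 2, mu1)
  n <- n0 + n1
  pooled <- crossprod(xc) / (n - 2)
  lambda <- if (identical(shrinkage, "analytic")) {
    analytic_shrinkage_intensity(t(xc))
  } else if (identical(shrinkage, "none")) 0 else shrinkage
  nu <- mean(diag(pooled))
  sigma <- (1 - lambda) * pooled + diag(lambda * nu, ncol(x))
  w <- tryCatch(solve(sigma, mu1 - mu0), error = function(e) {
    stop("pooled covariance is singular; enable shrinkage.", call. = FALSE)
  })
  structure(list(weights = as.numeric(w),
                 threshold = sum(w * (mu0 + mu1)) / 2,
                 means = rbind(mu0, mu1), levels = lev,
                 shrinkage = lambda),
            class = "lda_model")
}

#' Predict class labels from a fitted LDA model
#' @param object an `lda_model`.
#' @param newdata trials x features matrix.
#' @param ... unused.
#' @return vector of predicted labels (the model's two levels).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  score <- as.matrix(newdata) %*% object$weights
  object$levels[ifelse(score > object$threshold, 2L, 1L)]
}

# Stratified fold assignment: each class split evenly across k folds.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

#' Time-resolved cross-validated expectancy classification
#'
#' For every timepoint, classifies trials by a binary expectancy label from
#' all sensor amplitudes at that timepoint, using stratified k-fold
#' cross-validation. With `balance = "subsample"` the majority class is first
#' subsampled to the minority count (a fresh subsample per repeat), removing
#' the 75/25 base-rate artifact so that chance is 50%.
#'
#' @param dataset an [epoched_dataset()] (or list with a trials x sensors x
#'   timepoints `data` array).
#' @param labels binary per-trial labels (e.g.
#'   `schedule$visual_expected`).
#' @param k folds (default 10).
#' @param n_repeats subsample/CV repeats (default 2).
#' @param balance `"subsample"` (default) or `"none"`.
#' @param shrinkage passed to [fit_lda()].
#' @param seed integer seed.
#' @return an `accuracy_timecourse`: list with `accuracy` (per timepoint,
#'   averaged over folds and repeats), `time_ms`, `n_folds`, `n_repeats`,
#'   `chance = 0.5`.
#' @export
expectancy_timecourse <- function(dataset, labels, k = 10, n_repeats = 2,
                                  balance = c("subsample", "none"),
                                  shrinkage = "analytic", seed = 1L) {
  balance <- match.arg(balance)
  data <- dataset$data
  stopifnot(length(dim(data)) == 3L, dim(data)[1] == length(labels))
  labels <- as.logical(labels)
  n_time <- dim(data)[3]
  n_min <- min(table(labels))
  if (n_min < k) {
    stop(sprintf("minority class has %d trials; need at least k = %d.", n_min, k),
         call. = FALSE)
  }

  with_seed(seed, {
    acc_rep <- matrix(0, n_repeats, n_time)
    for (r in seq_len(n_repeats)) {
      if (balance == "subsample") {
        keep <- unlist(lapply(c(FALSE, TRUE), function(cl) {
          idx <- which(labels == cl)
          if (length(idx) > n_min) sample(idx, n_min) else idx
        }))
        keep <- sort(keep)
      } else {
        keep <- seq_along(labels)
      }
      y <- labels[keep]
      folds <- stratified_folds(y, k)
      correct <- matrix(0, k, n_time)
      count <- vapply(seq_len(k), function(f) sum(folds == f), integer(1))
      sub <- data[keep, , , drop = FALSE]
      for (t in seq_len(n_time)) {
        xt <- sub[, , t, drop = FALSE]
        dim(xt) <- dim(xt)[1:2]
        for (f in seq_len(k)) {
          test <- folds == f
          model <- fit_lda(xt[!test, , drop = FALSE], y[!test], shrinkage)
          pred <- predict(model, xt[test, , drop = FALSE])
          correct[f, t] <- sum(pred == y[test])
        }
      }
      acc_rep[r, ] <- colMeans(correct / count)
    }
    structure(list(accuracy = colMeans(acc_rep), time_ms = dataset$time_ms,
                   n_folds = k, n_repeats = n_repeats, chance = 0.5,
                   balance = balance, seed = seed),
              class = "accuracy_timecourse")
  })
}

#' @export
print.accuracy_timecourse <- function(x, ...) {
  cat(sprintf("Accuracy timecourse: %d timepoints, %d-fold CV x %d repeat(s)\n",
              length(x$accuracy), x$n_folds, x$n_repeats))
  cat(sprintf("  mean %.3f, max %.3f (chance %.2f)\n",
              mean(x$accuracy), max(x$accuracy), x$chance))
  invisible(x)
}

#' Cluster-corrected test of classification accuracy against chance
#'
#' One-sample cluster-mass permutation test (sign flipping of each subject's
#' deviation from chance) applied to per-subject accuracy time courses.
#'
#' @param accuracies subjects x timepoints matrix of accuracies, or a list of
#'   `accuracy_timecourse` objects.
#' @param chance chance level (default 0.5).
#' @param n_perm,cluster_alpha,seed passed to [cluster_onesample()].
#' @return a `cluster_result`.
#' @export
accuracy_vs_chance <- function(accuracies, chance = 0.5, n_perm = 1000,
                               cluster_alpha = 0.05, seed = 1L) {
  if (is.list(accuracies) && !is.matrix(accuracies)) {
    accuracies <- do.call(rbind, lapply(accuracies, function(a) a$accuracy))
  }
  cluster_onesample(accuracies, mu = chance, n_perm = n_perm,
                    cluster_alpha = cluster_alpha, seed = seed)
}
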