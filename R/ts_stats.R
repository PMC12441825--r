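# Per-timepoint 2x2 repeated-measures ANOVA with cluster-mass permutation
# correction and per-timepoint Bayes factors.
#
# The panel is a subjects x 4-cells x timepoints array (cells in the order
# VEME, VEMU, VUME, VUMU, i.e. A1B1, A1B2, A2B1, A2B2). For a 2-level
# within-subject effect the F at each timepoint equals the squared paired t
# on the per-subject contrast scores, which allows all timepoints (and all
# permutations) to be computed with a handful of matrix products.

EFFECT_CONTRASTS <- list(A = c(1, 1, -1, -1) / 2,
                         B = c(1, -1, 1, -1) / 2,
                         AxB = c(1, -1, -1, 1))

# All 24 permutations of the 4 cell labels, rows = permutations.
PERMS4 <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
PERMS4 <- PERMS4[apply(PERMS4, 1, function(r) length(unique(r)) == 4L), ,
                 drop = FALSE]
rownames(PERMS4) <- NULL

check_panel <- function(panel) {
  stopifnot(is.array(panel), length(dim(panel)) == 3L, dim(panel)[2] == 4L)
  if (anyNA(panel)) stop("panel must have no missing entries.", call. = FALSE)
  invisible(panel)
}

# F time courses from per-subject contrast scores d (subjects x timepoints):
# F(t) = n * mean(d_t)^2 / var(d_t), df = (1, n - 1).
contrast_f <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  f <- n * m^2 / v
  f[!is.finite(f)] <- 0
  f
}

#' Per-timepoint 2x2 repeated-measures F statistics
#'
#' Applies the 2x2 within-subject ANOVA independently at every timepoint of
#' a subjects x 4 x timepoints panel and returns the F time course of each
#' effect (visual main effect A, motor main effect B, interaction AxB), all
#' with `df = (1, n_subjects - 1)`.
#'
#' @param panel numeric array, subjects x 4 cells x timepoints, cells ordered
#'   `VEME, VEMU, VUME, VUMU`.
#' @return matrix timepoints x 3 with columns `A`, `B`, `AxB`.
#' @export
pointwise_f <- function(panel) {
  check_panel(panel)
  n_time <- dim(panel)[3]
  out <- matrix(0, n_time, 3, dimnames = list(NULL, names(EFFECT_CONTRASTS)))
  for (e in names(EFFECT_CONTRASTS)) {
    w <- EFFECT_CONTRASTS[[e]]
    d <- w[1] * panel[, 1, ] + w[2] * panel[, 2, ] +
      w[3] * panel[, 3, ] + w[4] * panel[, 4, ]
    if (is.null(dim(d))) d <- matrix(d, nrow = dim(panel)[1])
    out[, e] <- contrast_f(d)
  }
  out
}

# Maximum cluster mass in one F series given a suprathreshold mask.
max_run_mass <- function(f, mask) {
  if (!any(mask)) return(0)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  masses <- mapply(function(s, e) sum(f[s:e]), starts[r$values], ends[r$values])
  max(masses)
}

# Contiguous suprathreshold runs as a data frame of clusters.
find_clusters <- function(f, mask) {
  if (!any(mask)) {
    return(data.frame(start = integer(0), end = integer(0), mass = numeric(0)))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             mass = mapply(function(s, e) sum(f[s:e]), starts[keep], ends[keep]))
}

#' Cluster-mass permutation test for 2x2 time-series panels
#'
#' At every timepoint a 2x2 repeated-measures ANOVA is computed; clusters are
#' maximal runs of temporally adjacent points with `p < cluster_alpha`, and a
#' cluster's mass is the sum of its F values. The null distribution of each
#' effect is built by shuffling the four condition labels within each subject
#' (one shuffle per subject per permutation, applied identically across all
#' timepoints so temporal autocorrelation is preserved) and recording the
#' largest cluster mass of each permutation (0 when no cluster forms).
#' Corrected p-values use `(1 + #\{null >= mass\}) / (1 + n_perm)`; a cluster
#' is flagged significant when its mass exceeds the 95th percentile of the
#' null.
#'
#' @param panel subjects x 4 x timepoints array (cells `VEME, VEMU, VUME,
#'   VUMU`).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param cluster_alpha cluster-forming alpha (default 0.05).
#' @param seed integer seed for the label shuffles.
#' @return a `cluster_result`: per effect, a list with `f` (time course),
#'   `threshold`, `clusters` (data frame `start`, `end`, `mass`,
#'   `p_corrected`, `significant`) and `null_max_masses`.
#' @export
cluster_permutation <- function(panel, n_perm = 1000, cluster_alpha = 0.05,
                                seed = 1L) {
  check_panel(panel)
  n_subj <- dim(panel)[1]
  if (n_subj < 2) stop("at least 2 subjects are required.", call. = FALSE)
  if (n_perm < 100) stop("n_perm must be at least 100.", call. = FALSE)
  n_time <- dim(panel)[3]
  fcrit <- stats::qf(1 - cluster_alpha, 1, n_subj - 1)

  f_obs <- pointwise_f(panel)

  # sign patterns induced on each contrast by each of the 24 label shuffles
  sign_tabs <- lapply(EFFECT_CONTRASTS, function(w) {
    t(apply(PERMS4, 1, function(pr) w[pr]))
  })

  with_seed(seed, {
    perm_id <- matrix(sample.int(nrow(PERMS4), n_perm * n_subj, replace = TRUE),
                      n_perm, n_subj)
    null_max <- matrix(0, n_perm, length(EFFECT_CONTRASTS),
                       dimnames = list(NULL, names(EFFECT_CONTRASTS)))
    for (e in names(EFFECT_CONTRASTS)) {
      sum_d <- matrix(0, n_perm, n_time)
      sum_d2 <- matrix(0, n_perm, n_time)
      for (s in seq_len(n_subj)) {
        xs <- panel[s, , ]                      # 4 x timepoints
        if (is.null(dim(xs))) xs <- matrix(xs, nrow = 4L)
        ds <- sign_tabs[[e]][perm_id[, s], , drop = FALSE] %*% xs
        sum_d <- sum_d + ds
        sum_d2 <- sum_d2 + ds^2
      }
      m <- sum_d / n_subj
      v <- (sum_d2 - n_subj * m^2) / (n_subj - 1)
      f_perm <- n_subj * m^2 / v
      f_perm[!is.finite(f_perm)] <- 0
      mask <- f_perm > fcrit
      null_max[, e] <- vapply(seq_len(n_perm), function(p) {
        max_run_mass(f_perm[p, ], mask[p, ])
      }, numeric(1))
    }

    effects <- lapply(names(EFFECT_CONTRASTS), function(e) {
      cl <- find_clusters(f_obs[, e], f_obs[, e] > fcrit)
      null <- null_max[, e]
      q95 <- stats::quantile(null, 0.95, names = FALSE)
      cl$p_corrected <- vapply(cl$mass, function(m) {
        (1 + sum(null >= m)) / (1 + n_perm)
      }, numeric(1))
      cl$significant <- cl$mass > q95
      list(f = f_obs[, e], threshold = fcrit, clusters = cl,
           null_max_masses = null, null_q95 = q95)
    })
    names(effects) <- names(EFFECT_CONTRASTS)
    structure(list(effects = effects, n_perm = n_perm,
                   cluster_alpha = cluster_alpha, seed = seed,
                   df = c(1, n_subj - 1)),
              class = "cluster_result")
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation test: %d permutations, cluster alpha %.3f, df (%d, %d)\n",
              x$n_perm, x$cluster_alpha, x$df[1], x$df[2]))
  for (e in names(x$effects)) {
    cl <- x$effects[[e]]$clusters
    if (nrow(cl) == 0) {
      cat(sprintf("  %s: no clusters\n", e))
    } else {
      for (i in seq_len(nrow(cl))) {
        cat(sprintf("  %s: cluster [%d, %d] mass %.1f, p = %.4f%s\n", e,
                    cl$start[i], cl$end[i], cl$mass[i], cl$p_corrected[i],
                    if (cl$significant[i]) " *" else ""))
      }
    }
  }
  invisible(x)
}

#' Per-timepoint JZS Bayes factors for the two main effects
#'
#' At each timepoint, computes the paired JZS Bayes factor on each factor's
#' per-subject marginal means (averaging over the other factor).
#'
#' @param panel subjects x 4 x timepoints array.
#' @param rscale Cauchy prior scale (default `sqrt(2)/2`).
#' @return matrix timepoints x 2 with columns `A` and `B` (BF10 values).
#' @export
pointwise_bf <- function(panel, rscale = sqrt(2) / 2) {
  check_panel(panel)
  n_time <- dim(panel)[3]
  out <- matrix(NA_real_, n_time, 2, dimnames = list(NULL, c("A", "B")))
  margins <- list(A = list(c(1, 2), c(3, 4)), B = list(c(1, 3), c(2, 4)))
  for (e in names(margins)) {
    m1 <- apply(panel[, margins[[e]][[1]], , drop = FALSE], c(1, 3), mean)
    m2 <- apply(panel[, margins[[e]][[2]], , drop = FALSE], c(1, 3), mean)
    out[, e] <- vapply(seq_len(n_time), function(t) {
      bayes_factor_paired(m1[, t], m2[, t], rscale = rscale)
    }, numeric(1))
  }
  out
}

#' One-sample cluster-mass permutation test (sign flipping)
#'
#' Tests per-subject time courses against a reference value (e.g.
#' classification accuracy against chance 0.5) with the same cluster-mass
#' machinery: the statistic is the one-sample squared t (an F with
#' `df = (1, n - 1)`), and the null is built by randomly flipping the sign of
#' each subject's deviation from the reference.
#'
#' @param values subjects x timepoints matrix.
#' @param mu reference value (default 0.5).
#' @param n_perm number of sign-flip permutations.
#' @param cluster_alpha cluster-forming alpha.
#' @param seed integer seed.
#' @return a `cluster_result` with a single effect `mu`.
#' @export
cluster_onesample <- function(values, mu = 0.5, n_perm = 1000,
                              cluster_alpha = 0.05, seed = 1L) {
  values <- as.matrix(values)
  n_subj <- nrow(values)
  if (n_subj < 2) stop("at least 2 subjects are required.", call. = FALSE)
  n_time <- ncol(values)
  d <- values - mu
  fcrit <- stats::qf(1 - cluster_alpha, 1, n_subj - 1)
  f_obs <- contrast_f(d)

  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n_subj, replace = TRUE),
                    n_perm, n_subj)
    sum_d <- signs %*% d
    ss <- colSums(d^2)                 # invariant under sign flips
    m <- sum_d / n_subj
    v <- (rep(1, n_perm) %o% ss - n_subj * m^2) / (n_subj - 1)
    f_perm <- n_subj * m^2 / v
    f_perm[!is.finite(f_perm)] <- 0
    mask <- f_perm > fcrit
    null <- vapply(seq_len(n_perm), function(p) {
      max_run_mass(f_perm[p, ], mask[p, ])
    }, numeric(1))

    cl <- find_clusters(f_obs, f_obs > fcrit)
    q95 <- stats::quantile(null, 0.95, names = FALSE)
    cl$p_corrected <- vapply(cl$mass, function(mss) {
      (1 + sum(null >= mss)) / (1 + n_perm)
    }, numeric(1))
    cl$significant <- cl$mass > q95
    structure(list(effects = list(mu = list(f = f_obs, threshold = fcrit,
                                            clusters = cl,
                                            null_max_masses = null,
                                            null_q95 = q95)),
                   n_perm = n_perm, cluster_alpha = cluster_alpha, seed = seed,
                   df = c(1, n_subj - 1)),
              class = "cluster_result")
  })
}
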