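# 2x2 within-subject ANOVA, partial eta squared and JZS Bayes factors.

#' Partial eta squared from F and degrees of freedom
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, the effect-size measure
#' `SS_effect / (SS_effect + SS_error)` expressed through the F ratio.
#'
#' @param f F statistic(s).
#' @param df1 numerator degrees of freedom (default 1).
#' @param df2 denominator (error) degrees of freedom.
#' @return partial eta squared in `[0, 1]`.
#' @examples
#' partial_eta_sq(16.996, 1, 51)  # 0.250
#' @export
partial_eta_sq <- function(f, df1 = 1, df2) {
  f * df1 / (f * df1 + df2)
}

#' Two-by-two repeated-measures ANOVA
#'
#' Full within-subject decomposition for a 2x2 design: each effect (factor
#' A, factor B, A x B) is tested against its own effect-by-subject
#' interaction, `F = MS_effect / MS_error` with `df = (1, n - 1)`. Partial
#' eta squared and (optionally) the JZS Bayes factor of each effect's
#' paired contrast are attached.
#'
#' @param cell_means matrix of per-subject cell means, subjects x 4, columns
#'   ordered `(A1B1, A1B2, A2B1, A2B2)` — for the expectancy design,
#'   `VEME, VEMU, VUME, VUMU` with A = visual and B = motor expectancy.
#' @param bayes logical; also compute JZS Bayes factors (default TRUE).
#' @return an `anova_2x2`: data frame with rows `A`, `B`, `AxB` and columns
#'   `F`, `df1`, `df2`, `p`, `eta_p2`, `bf10`.
#' @export
rm_anova_2x2 <- function(cell_means, bayes = TRUE) {
  y <- as.matrix(cell_means)
  if (ncol(y) != 4L) stop("cell_means must have 4 columns (A1B1, A1B2, A2B1, A2B2).",
                          call. = FALSE)
  if (anyNA(y)) stop("missing cells are not allowed.", call. = FALSE)
  n <- nrow(y)
  if (n < 3) stop("at least 3 subjects are required.", call. = FALSE)

  grand <- mean(y)
  subj <- rowMeans(y)
  a_means <- c(mean(y[, 1:2]), mean(y[, 3:4]))       # A marginals
  b_means <- c(mean(y[, c(1, 3)]), mean(y[, c(2, 4)]))  # B marginals
  a_of <- c(1, 1, 2, 2)
  b_of <- c(1, 2, 1, 2)

  ss_a <- 2 * n * sum((a_means - grand)^2)
  ss_b <- 2 * n * sum((b_means - grand)^2)
  cell_grand <- colMeans(y)
  ss_ab <- n * sum((cell_grand - a_means[a_of] - b_means[b_of] + grand)^2)

  # subject-level marginal means
  subj_a <- cbind(rowMeans(y[, 1:2, drop = FALSE]), rowMeans(y[, 3:4, drop = FALSE]))
  subj_b <- cbind(rowMeans(y[, c(1, 3), drop = FALSE]), rowMeans(y[, c(2, 4), drop = FALSE]))
  ss_as <- 2 * sum((subj_a - outer(subj, rep(1, 2)) -
                      outer(rep(1, n), a_means) + grand)^2)
  ss_bs <- 2 * sum((subj_b - outer(subj, rep(1, 2)) -
                      outer(rep(1, n), b_means) + grand)^2)
  fitted_abs <- outer(rep(1, n), cell_grand) +
    (subj_a[, a_of] - outer(rep(1, n), a_means[a_of])) +
    (subj_b[, b_of] - outer(rep(1, n), b_means[b_of])) -
    (subj - grand)
  ss_abs <- sum((y - fitted_abs)^2)

  df2 <- n - 1
  f <- c(A = ss_a / (ss_as / df2),
         B = ss_b / (ss_bs / df2),
         AxB = ss_ab / (ss_abs / df2))
  # zero-variance error terms with zero effect: define F = 0
  f[!is.finite(f)] <- 0
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  out <- data.frame(effect = c("A", "B", "AxB"), F = unname(f),
                    df1 = 1, df2 = df2, p = unname(p),
                    eta_p2 = unname(partial_eta_sq(f, 1, df2)),
                    bf10 = NA_real_)
  if (bayes) {
    out$bf10 <- c(bayes_factor_paired(subj_a[, 1], subj_a[, 2]),
                  bayes_factor_paired(subj_b[, 1], subj_b[, 2]),
                  bayes_factor_paired(y[, 1] - y[, 2], y[, 3] - y[, 4]))
  }
  class(out) <- c("anova_2x2", "data.frame")
  out
}

#' JZS Bayes factor for a paired comparison
#'
#' Jeffreys-Zellner-Siow Bayes factor `BF10` for the paired t-test on
#' `x - y`, with a Cauchy prior of scale `r = sqrt(2)/2` on the standardised
#' effect size, computed by numerical integration over the prior on the
#' variance-scaling parameter g. Values above 1 favour a non-zero effect.
#'
#' Degenerate inputs (zero-variance differences) have no likelihood spread:
#' the function returns `Inf` when the mean difference is non-zero and `NaN`
#' when the differences are identically zero.
#'
#' @param x,y paired observation vectors (equal length, at least 3), or `y`
#'   omitted to test `x` against zero.
#' @param rscale Cauchy prior scale (default `sqrt(2)/2`).
#' @return the Bayes factor BF10 (scalar).
#' @export
bayes_factor_paired <- function(x, y = NULL, rscale = sqrt(2) / 2) {
  d <- if (is.null(y)) x else x - y
  n <- length(d)
  if (!is.null(y) && length(y) != n) stop("x and y must have equal length.", call. = FALSE)
  if (n < 3) stop("at least 3 pairs are required.", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) {
    return(if (mean(d) == 0) NaN else Inf)
  }
  t_stat <- mean(d) / (s / sqrt(n))
  jzs_bf10(t_stat, n, rscale)
}

# JZS BF10 from a one-sample t statistic (Rouder et al. 2009):
# BF10 = integral over g of the marginal likelihood ratio under the
# Cauchy(0, r) prior on delta, expressed via the inverse-gamma mixture.
jzs_bf10 <- function(t_stat, n, rscale = sqrt(2) / 2) {
  nu <- n - 1
  log_null <- -((nu + 1) / 2) * log1p(t_stat^2 / nu)
  integrand <- function(g) {
    a <- 1 + n * g * rscale^2
    exp(-0.5 * log(a) - ((nu + 1) / 2) * log1p(t_stat^2 / (a * nu)) - log_null +
          -1.5 * log(g) - 1 / (2 * g) - 0.5 * log(2 * pi))
  }
  int <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-9,
                          subdivisions = 500L)
  int$value
}
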