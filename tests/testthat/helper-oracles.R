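# Independent oracles used across the suite. Each reimplements the quantity
# it checks with a different, deliberately naive construction so the main
# code path is never compared against itself.

# circular orientation distance in [0, 90]
circ_dist <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

# naive matrix product via explicit triple loop
naive_matmul <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(b))) {
      s <- 0
      for (k in seq_len(ncol(a))) s <- s + a[i, k] * b[k, j]
      out[i, j] <- s
    }
  }
  out
}

# one-regressor least squares per sensor via lm()
oracle_forward <- function(b_train, c_i) {
  vapply(seq_len(nrow(b_train)), function(s) {
    unname(stats::coef(stats::lm(b_train[s, ] ~ 0 + c_i)))
  }, numeric(1))
}

# residual covariance and analytic shrinkage written as explicit sums
oracle_noise <- function(b_train, w_i, c_i) {
  n <- ncol(b_train)
  p <- nrow(b_train)
  eps <- b_train - outer(w_i, c_i)
  raw <- matrix(0, p, p)
  for (k in seq_len(n)) raw <- raw + outer(eps[, k], eps[, k])
  raw <- raw / (n - 1)
  s_n <- raw * (n - 1) / n
  nu <- mean(diag(s_n))
  d2 <- sum((s_n - diag(nu, p))^2)
  b2 <- 0
  for (k in seq_len(n)) b2 <- b2 + sum((outer(eps[, k], eps[, k]) - s_n)^2)
  b2 <- b2 / n^2
  lambda <- max(0, min(1, b2 / d2))
  nu_hat <- mean(diag(raw))
  list(raw = raw, shrunk = (1 - lambda) * raw + diag(lambda * nu_hat, p),
       lambda = lambda)
}

# spatial filter via explicit inverse
oracle_filter <- function(w, sigma) {
  si <- solve(sigma)
  as.numeric(si %*% w) / as.numeric(t(w) %*% si %*% w)
}

# 2x2 within-subject ANOVA through base aov() with an Error stratum
oracle_rm_anova <- function(cell_means) {
  n <- nrow(cell_means)
  df <- data.frame(
    y = as.vector(cell_means),
    subj = factor(rep(seq_len(n), 4)),
    A = factor(rep(c(1, 1, 2, 2), each = n)),
    B = factor(rep(c(1, 2, 1, 2), each = n)))
  fit <- stats::aov(y ~ A * B + Error(subj / (A * B)), data = df)
  sm <- summary(fit)
  getf <- function(stratum) sm[[stratum]][[1]][1, "F value"]
  c(A = getf("Error: subj:A"), B = getf("Error: subj:B"),
    AxB = getf("Error: subj:A:B"))
}

# JZS BF10 by dense trapezoid quadrature on a log-spaced grid
oracle_jzs_bf <- function(t_stat, n, rscale = sqrt(2) / 2) {
  nu <- n - 1
  g <- exp(seq(log(1e-8), log(1e8), length.out = 40000))
  f <- (1 + n * g * rscale^2)^(-0.5) *
    (1 + t_stat^2 / ((1 + n * g * rscale^2) * nu))^(-(nu + 1) / 2) *
    (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
  num <- sum(diff(g) * (f[-1] + f[-length(f)]) / 2)
  num / (1 + t_stat^2 / nu)^(-(nu + 1) / 2)
}

# tiny helper: schedule with n trials per cell by stacking matched schedules
balanced_schedule <- function(seed = 1) {
  match_trials(generate_schedule(10, 72, seed = seed))
}
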