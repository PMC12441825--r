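# Inverted encoding model: basis, estimation, filters, decoding.

test_that("basis tuning curves match the rectified fourth-power cosine", {
  b <- iem_basis()
  expect_equal(b$preferred_deg, c(0, 36, 72, 108, 144))

  r0 <- channel_responses(0, b)[, 1]
  side <- cos(72 * pi / 180)^4
  expect_equal(unname(r0), c(1, side, 0, 0, side), tolerance = 1e-10)
  expect_equal(unname(channel_responses(36, b)["ch36", 1]), 1)
  expect_equal(unname(channel_responses(36, b)["ch0", 1]), 0.00912,
               tolerance = 1e-3)

  # zero beyond 45 degrees of circular distance, range [0, 1]
  th <- seq(0, 179, by = 1)
  cr <- channel_responses(th, b)
  for (k in 1:5) {
    far <- circ_dist(th, b$preferred_deg[k]) >= 45
    # cos(pi/2) evaluates to ~6e-17, so "exactly zero" means below 1e-60 here
    expect_true(all(cr[k, far] < 1e-60))
  }
  expect_true(all(cr >= 0 & cr <= 1))

  # channel sum is invariant under 36-degree shifts of the stimulus
  expect_equal(colSums(channel_responses(th, b)),
               colSums(channel_responses(th + 36, b)))
})

test_that("centring removes presentation means and is idempotent", {
  x <- matrix(rnorm(60), 6, 10)
  x[2, ] <- 3                      # constant row maps to zero
  cx <- center_presentations(x)
  expect_true(all(abs(rowMeans(cx)) < 1e-12))
  expect_true(all(cx[2, ] == 0))
  expect_equal(center_presentations(cx), cx)
})

test_that("forward weights equal independent one-regressor least squares", {
  set.seed(10)
  # rank-1 noiseless data recovers the true weights exactly
  w_true <- rnorm(6)
  c1 <- center_presentations(matrix(rnorm(30), 1, 30))
  b1 <- outer(w_true, c1[1, ])
  expect_equal(fit_forward(b1, c1)[, 1], w_true, tolerance = 1e-12)

  # random data: per-channel result matches the lm() oracle
  B <- center_presentations(matrix(rnorm(6 * 40), 6, 40))
  C <- center_presentations(channel_responses(runif(40, 0, 180)))
  W <- fit_forward(B, C)
  for (i in 1:5) {
    expect_equal(W[, i], oracle_forward(B, C[i, ]), tolerance = 1e-10)
  }

  # a zero-variance channel is a singular normal equation
  C0 <- C; C0[3, ] <- 0
  expect_error(fit_forward(B, C0), "channel 3")
})

test_that("noise model matches the explicit-sum shrinkage oracle and stays SPD", {
  set.seed(11)
  B <- center_presentations(matrix(rnorm(5 * 60), 5, 60))
  C <- center_presentations(channel_responses(runif(60, 0, 180)))
  W <- fit_forward(B, C)
  for (i in c(1, 4)) {
    nm <- estimate_noise(B, W[, i], C[i, ])
    orc <- oracle_noise(B, W[, i], C[i, ])
    expect_equal(nm$raw_cov, orc$raw, tolerance = 1e-10)
    expect_equal(nm$shrinkage, orc$lambda, tolerance = 1e-10)
    expect_equal(nm$shrunk_cov, orc$shrunk, tolerance = 1e-10)
    expect_silent(chol(nm$shrunk_cov))
  }

  # shrinkage intensity always lies in [0, 1]
  for (k in 1:100) {
    eps <- matrix(rnorm(4 * 8, sd = runif(1, 0.1, 10)), 4, 8)
    lam <- estimate_noise(eps, rep(0, 4), rep(0, 8), "analytic")$shrinkage
    expect_true(lam >= 0 && lam <= 1)
  }

  # large-sample i.i.d. residuals give a covariance near the identity
  set.seed(12)
  eps <- matrix(rnorm(8 * 1e4), 8, 1e4)
  nm <- estimate_noise(eps, rep(0, 8), rep(0, 1e4))
  expect_lt(sqrt(sum((nm$shrunk_cov - diag(8))^2)), 0.1)

  # noiseless (zero-residual) training data degrade gracefully to identity
  c1 <- center_presentations(matrix(rnorm(20), 1, 20))
  b1 <- outer(c(1, 2, -1), c1[1, ])
  nm0 <- estimate_noise(b1, c(1, 2, -1), c1[1, ])
  expect_true(nm0$degenerate)
  v <- spatial_filter(c(1, 2, -1), nm0)
  expect_equal(v, c(1, 2, -1) / sum(c(1, 2, -1)^2))

  expect_error(estimate_noise(matrix(0, 3, 1), rep(0, 3), 0), "at least 2")
})

test_that("spatial filters satisfy unit gain and match the direct-inverse oracle", {
  # identity covariance reduces to w / (w'w)
  w <- c(2, -1, 0.5)
  expect_equal(spatial_filter(w, diag(3)), w / sum(w^2))

  # 2x2 hand computation: w = (1,0), Sigma = diag(2,1) -> v = (1, 0)
  expect_equal(spatial_filter(c(1, 0), diag(c(2, 1))), c(1, 0))

  set.seed(13)
  for (k in 1:100) {
    p <- sample(3:8, 1)
    w <- rnorm(p)
    sigma <- crossprod(matrix(rnorm(p * p), p)) + diag(p)
    v <- spatial_filter(w, sigma)
    expect_equal(sum(v * w), 1, tolerance = 1e-10)
    expect_equal(v, oracle_filter(w, sigma), tolerance = 1e-8)
  }
  expect_error(spatial_filter(c(1, 1), matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("reconstruction is the plain filter-by-data product", {
  set.seed(14)
  V <- matrix(rnorm(6 * 5), 6, 5)
  B <- matrix(rnorm(6 * 9), 6, 9)
  expect_equal(reconstruct(V, B), naive_matmul(t(V), B), tolerance = 1e-12)
  expect_true(all(reconstruct(V, matrix(0, 6, 3)) == 0))

  # orthogonal forward weights with identity covariance invert exactly
  W <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:5]
  Vf <- sapply(1:5, function(i) spatial_filter(W[, i], diag(6)))
  cvec <- runif(5)
  expect_equal(as.numeric(reconstruct(Vf, W %*% cvec)), cvec, tolerance = 1e-10)
})

test_that("the doubled-angle phasor decode handles one-hot, midpoint and cancelling inputs", {
  expect_equal(decode_orientation(c(0, 1, 0, 0, 0)), 36)
  expect_equal(decode_orientation(c(1, 1, 0, 0, 0)), 18)
  expect_true(is.na(decode_orientation(rep(1, 5))))
  expect_true(is.na(decode_orientation(rep(0, 5))))
  # matrix input decodes column-wise
  expect_equal(decode_orientation(diag(5)), c(0, 36, 72, 108, 144))
})

test_that("decoding accuracy is the projected mean resultant with doubled angles", {
  th <- runif(50, 0, 180)
  expect_equal(as.numeric(decoding_accuracy(th, th)), 1)
  expect_equal(as.numeric(decoding_accuracy((th + 90) %% 180, th)), -1)

  set.seed(15)
  a <- decoding_accuracy(runif(1e5, 0, 180), rep(45, 1e5))
  expect_lt(abs(as.numeric(a)), 0.02)

  # relabelling both arguments by a common rotation changes nothing
  dec <- runif(30, 0, 180)
  expect_equal(as.numeric(decoding_accuracy(dec, th[1:30])),
               as.numeric(decoding_accuracy((dec + 53) %% 180, (th[1:30] + 53) %% 180)),
               tolerance = 1e-12)

  # undefined decodes are excluded and counted; all-undefined is an error
  a2 <- decoding_accuracy(c(NA, th[1:3]), th[1:4])
  expect_equal(attr(a2, "n_undefined"), 1L)
  expect_error(decoding_accuracy(NA_real_, 10), "no defined")
})

test_that("every pipeline intermediate matches naive per-equation implementations", {
  set.seed(16)
  n <- 40; p <- 4
  th <- runif(n, 0, 180)
  B <- center_presentations(matrix(rnorm(p * n), p, n))
  C <- center_presentations(channel_responses(th))
  W <- fit_forward(B, C)
  for (i in 1:5) {
    w_o <- oracle_forward(B, C[i, ])
    expect_equal(W[, i], w_o, tolerance = 1e-8)
    nm <- estimate_noise(B, W[, i], C[i, ])
    orc <- oracle_noise(B, w_o, C[i, ])
    expect_equal(nm$shrunk_cov, orc$shrunk, tolerance = 1e-8)
    expect_equal(spatial_filter(W[, i], nm), oracle_filter(w_o, orc$shrunk),
                 tolerance = 1e-8)
  }
  V <- sapply(1:5, function(i) spatial_filter(W[, i], estimate_noise(B, W[, i], C[i, ])))
  expect_equal(reconstruct(V, B), naive_matmul(t(V), B), tolerance = 1e-8)
})

test_that("cross-validated decoding recovers strong signal and is deterministic", {
  sched <- generate_schedule(2, 80, seed = 5)
  ds <- simulate_eeg(sched, tuning_config(n_sensors = 16, snr = 100,
                                          signal_window_ms = c(0, 150)),
                     seed = 5, epoch_window_ms = c(-50, 150))
  dr <- crossvalidated_decode(ds, k = 10, seed = 1)
  pk <- which.max(ds$ground_truth$temporal_profile)
  expect_gt(dr$accuracy$overall[pk], 0.9)

  dr2 <- crossvalidated_decode(ds, k = 10, seed = 1)
  expect_identical(dr$decoded_deg, dr2$decoded_deg)
  expect_identical(dr$accuracy, dr2$accuracy)

  expect_error(crossvalidated_decode(ds, k = 200, seed = 1), "at least")
})

test_that("decoding is equivariant under stimulus rotations by the channel spacing", {
  # the basis repeats every 36 degrees, so rotating all orientations by 36
  # must rotate every decode by exactly 36 in the noiseless case; the sensor
  # embedding is taken orthonormal because the shrinkage target (sensor-space
  # identity) is only rotation-neutral under an isometric embedding
  set.seed(17)
  th <- runif(60, 0, 180)
  W_true <- qr.Q(qr(matrix(rnorm(8 * 8), 8)))[, 1:5]
  run <- function(orient) {
    B <- center_presentations(W_true %*% channel_responses(orient))
    C <- center_presentations(channel_responses(orient))
    W <- fit_forward(B, C)
    V <- sapply(1:5, function(i) {
      spatial_filter(W[, i], estimate_noise(B, W[, i], C[i, ]))
    })
    decode_orientation(reconstruct(V, B))
  }
  d0 <- run(th)
  d36 <- run((th + 36) %% 180)
  expect_true(all(circ_dist((d0 + 36) %% 180, d36) < 1e-6))
})
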