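# Per-timepoint ANOVA, cluster-mass permutation, per-timepoint Bayes factors.

make_panel <- function(n_subj = 20, n_time = 60, seed = 1) {
  set.seed(seed)
  array(rnorm(n_subj * 4 * n_time), c(n_subj, 4, n_time))
}

test_that("pointwise F equals a per-timepoint ANOVA loop and respects edge cases", {
  panel <- make_panel(12, 25, seed = 40)
  f <- pointwise_f(panel)
  for (t in c(1, 13, 25)) {
    expect_equal(unname(f[t, ]), rm_anova_2x2(panel[, , t], bayes = FALSE)$F,
                 tolerance = 1e-10)
  }
  # constant panel: all F are zero
  expect_true(all(pointwise_f(array(2, c(6, 4, 10))) == 0))
  # single-timepoint panel agrees with the direct ANOVA
  p1 <- panel[, , 1, drop = FALSE]
  expect_equal(unname(pointwise_f(p1)[1, ]),
               rm_anova_2x2(panel[, , 1], bayes = FALSE)$F, tolerance = 1e-10)
  expect_error(pointwise_f(array(NA_real_, c(4, 4, 3))), "missing")
})

test_that("cluster permutation finds no clusters in degenerate data and is deterministic", {
  const <- array(5, c(8, 4, 20))
  cr <- cluster_permutation(const, n_perm = 200, seed = 1)
  for (e in names(cr$effects)) {
    expect_equal(nrow(cr$effects[[e]]$clusters), 0L)
  }
  panel <- make_panel(10, 30, seed = 41)
  cr1 <- cluster_permutation(panel, n_perm = 300, seed = 2)
  cr2 <- cluster_permutation(panel, n_perm = 300, seed = 2)
  expect_identical(cr1, cr2)
  expect_error(cluster_permutation(panel, n_perm = 50, seed = 1), "at least 100")
})

test_that("an injected boxcar effect is detected over most of its window", {
  n_subj <- 20; n_time <- 100
  window <- 31:56                       # ~100 ms at 256 Hz
  hits <- 0; overlap_ok <- 0; n_seeds <- 50
  for (seed in seq_len(n_seeds)) {
    panel <- make_panel(n_subj, n_time, seed = 100 + seed)
    # visual main effect: +3 on A1 cells, -3 on A2 cells inside the window
    panel[, 1:2, window] <- panel[, 1:2, window] + 3
    panel[, 3:4, window] <- panel[, 3:4, window] - 3
    cr <- cluster_permutation(panel, n_perm = 500, seed = seed)
    cl <- cr$effects$A$clusters
    sig <- cl[cl$significant, , drop = FALSE]
    if (nrow(sig)) {
      hits <- hits + 1
      cover <- sum(sapply(seq_len(nrow(sig)), function(i) {
        length(intersect(sig$start[i]:sig$end[i], window))
      }))
      if (cover >= 0.8 * length(window)) overlap_ok <- overlap_ok + 1
    }
  }
  expect_gte(overlap_ok / n_seeds, 0.95)
})

test_that("cluster statistics are invariant to time reversal and constant shifts", {
  panel <- make_panel(15, 40, seed = 42)
  panel[, 1, 10:20] <- panel[, 1, 10:20] + 1.5   # some structure
  cr <- cluster_permutation(panel, n_perm = 400, seed = 3)
  rev_panel <- panel[, , 40:1]
  cr_rev <- cluster_permutation(rev_panel, n_perm = 400, seed = 3)
  for (e in names(cr$effects)) {
    expect_equal(cr$effects[[e]]$f, rev(cr_rev$effects[[e]]$f), tolerance = 1e-12)
    expect_equal(sort(cr$effects[[e]]$clusters$p_corrected),
                 sort(cr_rev$effects[[e]]$clusters$p_corrected))
    expect_equal(cr$effects[[e]]$null_max_masses,
                 cr_rev$effects[[e]]$null_max_masses, tolerance = 1e-9)
  }
  cr_shift <- cluster_permutation(panel + 7, n_perm = 400, seed = 3)
  for (e in names(cr$effects)) {
    expect_equal(cr$effects[[e]]$f, cr_shift$effects[[e]]$f, tolerance = 1e-9)
    expect_equal(cr$effects[[e]]$clusters$mass, cr_shift$effects[[e]]$clusters$mass,
                 tolerance = 1e-9)
  }
})

test_that("the permutation null distribution is stable in law across seed batches", {
  panel <- make_panel(15, 40, seed = 43)
  null1 <- cluster_permutation(panel, n_perm = 1000, seed = 10)$effects$A$null_max_masses
  null2 <- cluster_permutation(panel, n_perm = 1000, seed = 20)$effects$A$null_max_masses
  ks <- suppressWarnings(stats::ks.test(null1, null2))
  expect_gt(ks$p.value, 0.01)
})

test_that("pointwise Bayes factors agree with the paired BF and track injected effects", {
  panel <- make_panel(20, 15, seed = 44)
  bf <- pointwise_bf(panel)
  m1 <- rowMeans(panel[, 1:2, 7]); m2 <- rowMeans(panel[, 3:4, 7])
  expect_equal(unname(bf[7, "A"]), bayes_factor_paired(m1, m2), tolerance = 1e-10)

  # null data: most timepoints favour the null
  expect_lt(stats::median(bf), 1)

  # a large injected effect produces strong evidence inside its window
  panel[, c(1, 3), 3:5] <- panel[, c(1, 3), 3:5] + 2
  bf2 <- pointwise_bf(panel)
  expect_true(all(bf2[3:5, "B"] > 10))
})

test_that("the one-sample sign-flip variant behaves at the null and under strong effects", {
  # all-equal accuracies at chance: statistic identically zero, no clusters
  flat <- matrix(0.5, 12, 30)
  cr0 <- cluster_onesample(flat, mu = 0.5, n_perm = 200, seed = 1)
  expect_true(all(cr0$effects$mu$f == 0))
  expect_equal(nrow(cr0$effects$mu$clusters), 0L)

  # strong deviation is found
  set.seed(45)
  vals <- matrix(0.5 + rnorm(12 * 30, 0, 0.02), 12, 30)
  vals[, 10:18] <- vals[, 10:18] + 0.2
  cr1 <- cluster_onesample(vals, mu = 0.5, n_perm = 500, seed = 2)
  sig <- cr1$effects$mu$clusters
  expect_true(any(sig$significant))

  # null false-positive rate stays near the nominal level
  fp <- 0; n_runs <- 100
  for (r in seq_len(n_runs)) {
    set.seed(500 + r)
    null_vals <- matrix(0.5 + rnorm(20 * 60, 0, 0.05), 20, 60)
    cr <- cluster_onesample(null_vals, mu = 0.5, n_perm = 500, seed = r)
    if (any(cr$effects$mu$clusters$significant)) fp <- fp + 1
  }
  expect_gte((n_runs - fp) / n_runs, 0.93)
})
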