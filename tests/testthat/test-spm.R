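test_that("cubic time-normalization reproduces linear and half-sine pushes", {
  fs <- 200
  # linear ramp 0 -> 8 Nm across a push
  torque <- numeric(400)
  torque[101:170] <- seq(0.1, 8, length.out = 70)
  sig <- make_signal(torque, fs = fs)
  pushes <- detect_pushes(sig, boundary_trim_frac = 0)
  prof <- suppressWarnings(normalize_pushes(sig, pushes, "torque", Q = 101))
  expect_equal(prof$values[1], 0.1, tolerance = 1e-9)
  expect_equal(prof$values[101], 8, tolerance = 1e-9)
  # linearity preserved by cubic interpolation
  mid <- (prof$values[1] + prof$values[101]) / 2
  expect_equal(prof$values[51], mid, tolerance = 1e-6)

  # half-sine template: node values match the analytic curve within 1e-3
  p <- quiet_params(block_duration = 40, peak_torque = 8)
  s <- generate_wheel_session(p)
  pu <- detect_pushes(s$signal)
  pr <- suppressWarnings(normalize_pushes(s$signal, pu, "torque", Q = 101))
  # node 0 sits on the first sampled (not the limiting) point of the push,
  # half a sample period in: compare against the template on that window
  u0 <- 0.5 / 70
  u <- seq(u0, 1 - u0, length.out = 101)
  expect_lt(max(abs(pr$values / 8 - sin(pi * u))), 1e-3)
})

test_that("identical pushes average to any single push profile", {
  p <- quiet_params(block_duration = 40)
  s <- generate_wheel_session(p)
  pu <- detect_pushes(s$signal)
  pr <- normalize_pushes(s$signal, pu, "torque", Q = 51, n_last = 20)
  expect_equal(pr$values, pr$per_push[1, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_warning(normalize_pushes(s$signal, pu[1:3, ], n_last = 20),
                 "using all")
})

test_that("the pointwise SPM t equals the scalar paired t at every node", {
  set.seed(61)
  ya <- smooth_gaussian_fields(9, 41, fwhm = 10)
  yb <- smooth_gaussian_fields(9, 41, fwhm = 10) + 0.3
  sp <- spm_paired_t(ya, yb)
  for (q in c(1, 7, 20, 41)) {
    tt <- t.test(ya[, q], yb[, q], paired = TRUE)
    expect_equal(sp$t[q], unname(tt$statistic), tolerance = 1e-10)
  }
  expect_equal(sp$df, 8)
})

test_that("the RFT threshold collapses to the scalar critical value for
           maximally smooth fields", {
  d <- outer(rnorm(10, 1), rep(1, 101))          # flat difference fields
  sp <- spm_paired_t(d, matrix(0, 10, 101))
  expect_equal(sp$resels, 0)
  expect_equal(sp$t_critical, qt(0.975, 9), tolerance = 1e-9)
  # and the threshold grows with the search volume
  expect_gt(rft_threshold(0.05, 9, resels = 10), rft_threshold(0.05, 9, 1))
})

test_that("identical inputs produce no clusters", {
  set.seed(71)
  y <- smooth_gaussian_fields(8, 101, 20)
  sp <- suppressWarnings(spm_paired_t(y, y))
  expect_equal(nrow(sp$clusters), 0L)
  pe <- suppressWarnings(spm_permutation(y, y, n_perm = 200))
  expect_equal(nrow(pe$clusters), 0L)
})

test_that("exhaustive and sampled permutation thresholds agree", {
  set.seed(81)
  ya <- smooth_gaussian_fields(10, 101, 20)
  yb <- smooth_gaussian_fields(10, 101, 20)
  exh <- spm_permutation(ya, yb, n_perm = 1024)       # 2^10: all sign flips
  expect_true(exh$exhaustive)
  smp <- spm_permutation(ya, yb, n_perm = 800, rng_seed = 2)
  expect_false(smp$exhaustive)
  expect_lt(abs(exh$t_critical - smp$t_critical) / exh$t_critical, 0.10)
})

test_that("RFT and permutation thresholds agree within 10% on smooth fields", {
  ratios <- sapply(1:4, function(seed) {
    ya <- smooth_gaussian_fields(12, 101, 20, rng_seed = seed)
    yb <- smooth_gaussian_fields(12, 101, 20, rng_seed = seed + 100)
    rft <- spm_paired_t(ya, yb)
    per <- spm_permutation(ya, yb, n_perm = 1000, rng_seed = seed)
    per$t_critical / rft$t_critical
  })
  expect_lt(mean(abs(ratios - 1)), 0.10)
})

test_that("a localized effect is flagged by both RFT and permutation", {
  set.seed(91)
  n <- 12; Q <- 101
  bump <- exp(-((seq(0, 100, length.out = Q) - 17)^2) / (2 * 4^2))
  ya <- smooth_gaussian_fields(n, Q, 20) + 3.5 * rep(1, n) %o% bump
  yb <- smooth_gaussian_fields(n, Q, 20)
  rft <- spm_paired_t(ya, yb)
  per <- spm_permutation(ya, yb, n_perm = 1000, rng_seed = 7)
  overlaps <- function(cl) {
    any(cl$start_pct <= 25 & cl$end_pct >= 10)
  }
  expect_true(overlaps(rft$clusters))
  expect_true(overlaps(per$clusters))
  expect_true(all(rft$clusters$p <= 0.05))
})

test_that("cluster extents in % of push phase are stable in Q (51 vs 101)", {
  # same continuous realization seen at two resolutions: Q = 51 subsamples
  # the Q = 101 grid at every other node
  n <- 10
  u <- seq(0, 100, length.out = 101)
  bump <- exp(-((u - 15)^2) / (2 * 5^2))
  ya <- smooth_gaussian_fields(n, 101, fwhm = 20, rng_seed = 5) +
    3.5 * rep(1, n) %o% bump
  yb <- smooth_gaussian_fields(n, 101, fwhm = 20, rng_seed = 6)
  sub <- seq(1, 101, by = 2)
  s101 <- spm_paired_t(ya, yb)
  s51 <- spm_paired_t(ya[, sub], yb[, sub])
  expect_gt(nrow(s101$clusters), 0)
  expect_gt(nrow(s51$clusters), 0)
  expect_lt(abs(s51$clusters$start_pct[1] - s101$clusters$start_pct[1]), 2)
  expect_lt(abs(s51$clusters$end_pct[1] - s101$clusters$end_pct[1]), 2)
})

test_that("zero-variance nodes are masked with a warning", {
  set.seed(111)
  ya <- smooth_gaussian_fields(8, 51, 10)
  yb <- smooth_gaussian_fields(8, 51, 10)
  ya[, 10] <- yb[, 10] <- 1                      # no variance at node 10
  expect_warning(sp <- spm_paired_t(ya, yb), "zero-variance")
  expect_true(is.na(sp$t[10]))
})
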