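test_that("identical columns with between-subject variance give ICC = 1", {
  x <- cbind(c(3, 7, 2, 9, 5, 6), c(3, 7, 2, 9, 5, 6))
  res <- icc_2_1(x)
  expect_equal(res$icc, 1)
  expect_equal(res$label, "excellent")
})

test_that("ICC(2,1) equals an independent mean-squares computation", {
  tables <- list(
    cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2)),
    cbind(c(1, 2, 3, 4, 5, 6), c(2, 2, 4, 4, 6, 7)),
    cbind(c(5, 5, 6, 8, 3, 9), c(6, 4, 7, 8, 2, 10)))
  for (x in tables) {
    expect_equal(icc_2_1(x)$icc, icc21_oracle(x), tolerance = 1e-10)
  }
  # and on random real-valued tables
  set.seed(11)
  for (i in 1:5) {
    x <- matrix(rnorm(24), 8, 3) + rnorm(8)
    expect_equal(icc_2_1(x)$icc, icc21_oracle(x), tolerance = 1e-10)
  }
})

test_that("ICC is shift-invariant overall but drops under a column shift", {
  set.seed(21)
  x <- matrix(rnorm(20), 10, 2) + 2 * rnorm(10)
  base <- icc_2_1(x)$icc
  expect_equal(icc_2_1(x + 7)$icc, base, tolerance = 1e-12)
  shifted <- x; shifted[, 2] <- shifted[, 2] + 2
  expect_lt(icc_2_1(shifted)$icc, base)
})

test_that("Monte-Carlo simulation recovers a population ICC of 0.85", {
  set.seed(8675309)
  n <- 30
  est <- replicate(500, {
    subj <- rnorm(n, sd = sqrt(0.85))
    x <- cbind(subj + rnorm(n, sd = sqrt(0.15)),
               subj + rnorm(n, sd = sqrt(0.15)))
    icc_2_1(x)$icc
  })
  se <- sd(est) / sqrt(length(est))
  # small-sample estimator bias is O(1/n); allow it on top of 3 SE
  expect_lt(abs(mean(est) - 0.85), 3 * se + 0.01)
})

test_that("degenerate tables are reported as undefined, not as numbers", {
  x <- matrix(5, 6, 2)                     # no variance anywhere
  res <- icc_2_1(x)
  expect_true(is.na(res$icc))
  expect_equal(res$label, "undefined")
  expect_error(icc_2_1(cbind(1:2, 1:2)), "at least 3")
})

test_that("RM-ANOVA matches the hand-expanded sums of squares", {
  x <- cbind(c(5, 3, 8, 4, 7), c(6, 4, 9, 4, 8), c(8, 5, 10, 6, 9))
  res <- omnibus_test(x, force = "anova")
  ora <- rm_anova_oracle(x)
  expect_equal(res$statistic, ora$F, tolerance = 1e-10)
  expect_equal(res$p, ora$p, tolerance = 1e-10)
  expect_equal(res$df, c(2, 8))
})

test_that("three identical columns give F = 0 and p = 1", {
  x <- cbind(c(1, 5, 3, 8), c(1, 5, 3, 8), c(1, 5, 3, 8))
  res <- omnibus_test(x, force = "anova")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("the Friedman statistic matches its closed form on rank tables", {
  x <- rbind(c(1, 2, 3), c(2, 3, 1), c(1, 3, 2), c(3, 2, 1))
  res <- omnibus_test(x, force = "friedman")
  expect_equal(res$statistic, friedman_oracle(x), tolerance = 1e-10)
  expect_equal(res$df, 2)
})

test_that("paired t omnibus equivalence holds at k = 2 (F = t^2)", {
  set.seed(31)
  for (i in 1:5) {
    x <- matrix(rnorm(16, mean = c(0, 0.8)), 8, 2, byrow = TRUE)
    f <- omnibus_test(x, force = "anova")
    tt <- t.test(x[, 1], x[, 2], paired = TRUE)
    expect_equal(f$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(f$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("paired Cohen's d is mean over SD of the differences", {
  a <- c(5, 8, 11); b <- a - c(2, 4, 6)
  res <- pairwise_tests(cbind(A = a, B = b), parametric = TRUE)
  expect_equal(res$effect_size, 2.0, tolerance = 1e-12)
  expect_equal(res$effect_band, "large")
})

test_that("six uniformly signed differences give the exact Wilcoxon p", {
  a <- c(2, 3, 5, 7, 9, 11); b <- a - c(1, 2, 3, 4, 5, 6)
  res <- pairwise_tests(cbind(A = a, B = b), parametric = FALSE)
  expect_equal(res$p, 0.03125, tolerance = 1e-12)
  expect_equal(res$effect_size, 1.0)
  # symmetric differences give r = 0
  d <- c(-3, -2, -1, 1, 2, 3)
  res2 <- pairwise_tests(cbind(A = d, B = rep(0, 6)), parametric = FALSE)
  expect_equal(res2$effect_size, 0)
})

test_that("exact Wilcoxon p-values match full enumeration for n <= 10", {
  set.seed(41)
  for (i in 1:5) {
    d <- round(rnorm(8, 0.5), 2)
    d <- d[d != 0]
    res <- pairwise_tests(cbind(A = d, B = 0), parametric = FALSE)
    expect_equal(res$p, wilcoxon_exact_oracle(d), tolerance = 1e-10)
  }
})

test_that("zero-variance differences flag an undefined effect size", {
  x <- cbind(A = c(1, 2, 3, 4), B = c(0, 1, 2, 3))
  expect_warning(res <- pairwise_tests(x, parametric = TRUE), "undefined")
  expect_true(is.na(res$effect_size))
})

test_that("the agreement report binds ICC, omnibus and pairwise pieces", {
  set.seed(51)
  subj <- rnorm(12, sd = 1.5)
  x <- cbind(OG = subj + rnorm(12, 0.0, 0.4),
             TM = subj + rnorm(12, -0.6, 0.4),
             WE = subj + rnorm(12, 0.2, 0.4))
  rep3 <- agreement_report(x, variable = "demo")
  expect_length(rep3$icc, 3L)
  expect_false(is.null(rep3$omnibus))
  # with two conditions there is no omnibus, only the paired comparison
  rep2 <- agreement_report(x[, 1:2], variable = "demo")
  expect_null(rep2$omnibus)
  expect_equal(nrow(rep2$pairwise), 1L)
})
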