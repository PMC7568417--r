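# Independent oracles and small fixtures shared across test files.

# quiet zero-noise session parameters with a short block
quiet_params <- function(..., neg_work_per_cycle = 0) {
  session_params(noise_sd_force = 0, noise_sd_torque = 0,
                 neg_work_per_cycle = neg_work_per_cycle, ...)
}

# ICC(2,1) by an independent route: mean squares from a two-way fixed-model
# aov() decomposition, plugged into the agreement formula written out here.
icc21_oracle <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(y = as.vector(x),
                  subj = factor(rep(seq_len(n), k)),
                  cond = factor(rep(seq_len(k), each = n)))
  ms <- anova(stats::lm(y ~ subj + cond, data = d))[["Mean Sq"]]
  msr <- ms[1L]; msc <- ms[2L]; mse <- ms[3L]
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# exact two-sided Wilcoxon signed-rank p by full enumeration of sign flips
wilcoxon_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# repeated-measures ANOVA F by hand-expanded sums of squares
rm_anova_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ss_cond <- n * sum((colMeans(x) - grand)^2)
  ss_subj <- k * sum((rowMeans(x) - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(F = f, p = stats::pf(f, k - 1, (n - 1) * (k - 1), lower.tail = FALSE))
}

# Friedman chi-squared from the closed-form rank statistic
friedman_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  r <- t(apply(x, 1L, rank))
  12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
}

# build a wheel_signal with constant angular velocity and given torque
make_signal <- function(torque, fs = 200, omega = 2, fef = NULL,
                        wheel_radius = 0.3, rim_radius = 0.27) {
  n <- length(torque)
  t <- (seq_len(n) - 1L) / fs
  angle <- omega * t
  if (is.null(fef)) {
    fx <- torque / rim_radius; fy <- numeric(n); fz <- numeric(n)
  } else {
    f <- fef / 100
    fx <- torque / rim_radius
    res <- abs(fx) * sqrt(1 / f^2 - 1)
    fy <- res / sqrt(2); fz <- res / sqrt(2)
  }
  wheel_signal(time = t, angle = angle, fx = fx, fy = fy, fz = fz,
               torque = torque, sample_rate = fs,
               wheel_radius = wheel_radius, rim_radius = rim_radius)
}
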