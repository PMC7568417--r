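test_that("zero-noise generation yields the configured pushes exactly", {
  p <- quiet_params(block_duration = 6, push_time = 0.35, cycle_time = 1.43)
  s <- generate_wheel_session(p)
  # onsets at 0.0025 + k * 1.43 must complete (push end <= 6 s): k = 0..3
  expect_identical(s$truth$n_pushes, 4L)
  pushes <- detect_pushes(s$signal)
  expect_equal(nrow(pushes), 4L)
  expect_equal(pushes$push_time, rep(0.35, 4))
  expect_equal(pushes$cycle_time[1:3], rep(1.43, 3))
})

test_that("half-sine work per push matches the analytic integral", {
  ca_deg <- 1.2 * 180 / pi
  p <- quiet_params(block_duration = 6, peak_torque = 8,
                    contact_angle = ca_deg)
  s <- generate_wheel_session(p)
  expect_equal(s$truth$work_per_push, 2 / pi * 8 * 1.2, tolerance = 1e-12)
  # and the pipeline-measured work agrees with the analytic value
  pushes <- detect_pushes(s$signal)
  expect_equal(mean(pushes$work), 2 / pi * 8 * 1.2, tolerance = 1e-3)
})

test_that("skewed template ground truth matches numeric integration", {
  p <- quiet_params(block_duration = 6, push_shape = "skewed",
                    shape_rise = 2.5, shape_fall = 1.3, peak_torque = 6)
  s <- generate_wheel_session(p)
  u <- seq(0, 1, length.out = 20001)
  f <- u^2.5 * (1 - u)^1.3
  f <- f / max(f)
  mean_num <- mean(f) * 6            # numeric mean torque of the template
  expect_equal(s$truth$mean_torque, mean_num, tolerance = 1e-4)
  expect_equal(s$truth$max_torque, 6)
})

test_that("generation is bit-reproducible under a fixed seed", {
  p1 <- session_params(block_duration = 5, rng_seed = 42)
  p2 <- session_params(block_duration = 5, rng_seed = 42)
  s1 <- generate_wheel_session(p1)
  s2 <- generate_wheel_session(p2)
  expect_identical(s1$signal$torque, s2$signal$torque)
  expect_identical(s1$signal$fx, s2$signal$fx)
  p3 <- session_params(block_duration = 5, rng_seed = 43)
  expect_false(identical(generate_wheel_session(p3)$signal$torque,
                         s1$signal$torque))
})

test_that("invalid session parameters fail naming the offending field", {
  expect_error(session_params(push_time = 1.5, cycle_time = 1.4),
               "push_time")
  expect_error(session_params(fef_target = 120), "fef_target")
  expect_error(session_params(rim_radius = 0.31, wheel_radius = 0.30),
               "rim_radius")
  expect_error(session_params(sample_rate = -10), "sample_rate")
  expect_error(session_params(neg_work_per_cycle = 1), "neg_work_per_cycle")
  expect_error(session_params(contact_angle = 400, target_speed = 0.9),
               "contact_angle")
})

test_that("block mean speed matches the target within 0.5%", {
  for (seed in 1:3) {
    p <- session_params(block_duration = 120, target_speed = 1.11,
                        rng_seed = seed)
    s <- generate_wheel_session(p)
    n <- length(s$signal$time)
    v <- p$wheel_radius * (s$signal$angle[n] - s$signal$angle[1L]) /
      (s$signal$time[n] - s$signal$time[1L])
    expect_lt(abs(v - 1.11) / 1.11, 0.005)
  }
})

test_that("coast-down traces have the constructed decelerations", {
  cd <- generate_coastdown(mass = 91.6, friction_coefficient = 0.01,
                           slope_bias = 0, noise_sd = 0)
  slopes <- sapply(cd, function(tr) {
    unname(coef(lm(velocity_ms ~ time_s, data = tr))[2L])
  })
  expect_equal(unname(slopes), c(-0.0981, -0.0981), tolerance = 1e-10)
  cd2 <- generate_coastdown(mass = 91.6, friction_coefficient = 0.01,
                            slope_bias = 0.02, noise_sd = 0)
  slopes2 <- sapply(cd2, function(tr) {
    unname(coef(lm(velocity_ms ~ time_s, data = tr))[2L])
  })
  expect_equal(abs(diff(unname(slopes2))), 0.04, tolerance = 1e-10)
  expect_true(all(cd$forward$velocity_ms > 0))
  expect_error(generate_coastdown(mass = -1, friction_coefficient = 0.01),
               "mass")
})

test_that("breath series reaches steady state and rises monotonically", {
  b <- generate_breath_data(vo2_ss = 1.2, rer_ss = 0.9, hr_ss = 94.49,
                            tau = 30, duration = 240, noise_sd_vo2 = 0,
                            noise_sd_hr = 0)
  last <- b[b$time_s > 180, ]
  expect_lt(abs(mean(last$vo2_Lmin) - 1.2) / 1.2, 0.01)
  expect_equal(b$vco2_Lmin / b$vo2_Lmin, rep(0.9, nrow(b)),
               tolerance = 1e-12)
  m3 <- mean(b$vo2_Lmin[b$time_s > 120 & b$time_s <= 180])
  m4 <- mean(b$vo2_Lmin[b$time_s > 180 & b$time_s <= 240])
  expect_lt(m3, m4)
  expect_lt(abs(mean_heart_rate(b) - 94.49), 0.2)
})
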