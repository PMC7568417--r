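test_that("square-wave pulses are segmented with exact durations", {
  fs <- 200
  torque <- numeric(3000)
  starts <- c(301, 801, 1301)
  for (s in starts) torque[s:(s + 69)] <- 5     # 70 samples = 0.35 s
  sig <- make_signal(torque, fs = fs, omega = 2)
  pushes <- detect_pushes(sig)
  expect_equal(nrow(pushes), 3L)
  expect_equal(pushes$push_time, rep(0.35, 3))
  expect_equal(pushes$cycle_time[1:2], rep(2.5, 2))
  # constant torque: work = mean_torque * contact_angle (rad), exactly
  ca_rad <- pushes$contact_angle * pi / 180
  expect_equal(pushes$work, pushes$mean_torque * ca_rad, tolerance = 1e-12)
})

test_that("an all-zero torque signal yields an empty push table", {
  sig <- make_signal(numeric(500))
  pushes <- detect_pushes(sig)
  expect_s3_class(pushes, "push_table")
  expect_equal(nrow(pushes), 0L)
})

test_that("constant-torque work and contact angle match hand values", {
  fs <- 200
  # 5 Nm while the wheel advances 1.0 rad: omega * 70/fs = 1.0
  omega <- 1.0 / (70 / fs)
  torque <- numeric(1000); torque[301:370] <- 5
  sig <- make_signal(torque, fs = fs, omega = omega)
  pushes <- detect_pushes(sig)
  expect_equal(nrow(pushes), 1L)
  expect_equal(pushes$work, 5.0, tolerance = 1e-12)
  # angle advance of 1.2 rad -> contact angle 68.75 degrees
  omega2 <- 1.2 / (70 / fs)
  sig2 <- make_signal(torque, fs = fs, omega = omega2)
  p2 <- detect_pushes(sig2)
  expect_equal(p2$contact_angle, 1.2 * 180 / pi, tolerance = 1e-12)
  expect_equal(round(p2$contact_angle, 2), 68.75)
})

test_that("constant power integrates to T * omega and zero negative work", {
  fs <- 200
  torque <- numeric(2000)
  torque[c(201:400, 1001:1200)] <- 5             # two long pushes
  sig <- make_signal(torque, fs = fs, omega = 2)
  bm <- block_metrics(sig, detect_pushes(sig))
  # between push starts the torque is 5 then 0: time-average over the span
  # from start 1 to start 2 is 5 * 2 W weighted by duty cycle 200/800
  expect_equal(bm$negative_work_per_cycle, 0)
  expect_equal(bm$speed, 0.3 * 2, tolerance = 1e-12)
  # near-constant torque across the analyzed span: power ~ T * omega = 10 W
  sig3 <- make_signal(c(0, rep(5, 400), 0, rep(5, 400), 0), fs = fs,
                      omega = 2)
  bm3 <- block_metrics(sig3, detect_pushes(sig3))
  expect_equal(bm3$power_output, 10, tolerance = 0.01)
})

test_that("FEF is recovered exactly at zero noise and capped at 100", {
  p <- quiet_params(block_duration = 10, fef_target = 75)
  s <- generate_wheel_session(p)
  pushes <- detect_pushes(s$signal)
  expect_lt(max(abs(pushes$fef - 75)), 0.5)
  # purely tangential force at the rim -> FEF = 100
  torque <- numeric(500); torque[101:170] <- 4
  sig <- make_signal(torque)                     # fx = T / rim only
  pu <- detect_pushes(sig)
  expect_equal(pu$fef, 100, tolerance = 1e-9)
  expect_equal(detect_pushes(sig, fef_mode = "mean_of_ratios")$fef, 100,
               tolerance = 1e-9)
})

test_that("push timings are recovered within one sample across cadences", {
  grid <- data.frame(push = c(0.29, 0.35, 0.41), cycle = c(1.17, 1.43, 0.97))
  for (i in seq_len(nrow(grid))) {
    p <- quiet_params(block_duration = 20, push_time = grid$push[i],
                      cycle_time = grid$cycle[i], contact_angle = 60,
                      start_offset = 0.0013)     # deliberately off-grid
    s <- generate_wheel_session(p)
    pushes <- detect_pushes(s$signal)
    expect_equal(nrow(pushes), s$truth$n_pushes)
    expect_lt(max(abs(pushes$push_time - grid$push[i])), 1 / 200 + 1e-9)
  }
})

test_that("an OG-like zero-noise session recovers ground truth within 1%", {
  p <- quiet_params(block_duration = 120, neg_work_per_cycle = -1.44,
                    target_speed = 1.12)
  s <- generate_wheel_session(p)
  win <- last_minute_window(s$signal)
  filt <- lowpass_filter(win)
  bm <- block_metrics(filt, detect_pushes(filt))
  tr <- s$truth
  rel <- function(est, tv) abs(est - tv) / abs(tv)
  expect_lt(rel(bm$push_time, tr$push_time), 0.01)
  expect_lt(rel(bm$cycle_time, tr$cycle_time), 0.01)
  expect_lt(rel(bm$contact_angle, tr$contact_angle), 0.01)
  expect_lt(rel(bm$work_per_push, tr$work_per_push), 0.01)
  expect_lt(rel(bm$fef, tr$fef), 0.01)
  expect_lt(rel(bm$power_output, tr$power_output), 0.01)
  expect_lt(rel(bm$mean_torque, tr$mean_torque), 0.01)
  expect_lt(rel(bm$speed, tr$speed), 0.005)
})

test_that("filtering changes metrics of a band-limited signal by < 1%", {
  fs <- 200
  t <- (0:5999) / fs
  torque <- 6 * sin(2 * pi * 1 * t)              # 1 Hz, pure tone
  sig <- make_signal(torque, fs = fs, omega = 3)
  raw <- block_metrics(sig, detect_pushes(sig))
  fl <- lowpass_filter(sig)
  fb <- block_metrics(fl, detect_pushes(fl))
  for (v in c("push_time", "mean_torque", "work_per_push",
              "contact_angle")) {
    expect_lt(abs(fb[[v]] - raw[[v]]) / abs(raw[[v]]), 0.01)
  }
})

test_that("the last-minute window slices and masks correctly", {
  p <- quiet_params(block_duration = 240)
  s <- generate_wheel_session(p)
  w <- last_minute_window(s$signal)
  expect_equal(diff(range(w$time)), 60, tolerance = 1e-9)
  expect_equal(max(w$time), max(s$signal$time))

  short <- quiet_params(block_duration = 59, cycle_time = 1.43)
  expect_error(last_minute_window(generate_wheel_session(short)$signal),
               "shorter")

  # straight-segment mask covering 70% of the window
  t_end <- max(s$signal$time)
  straights <- data.frame(start_s = t_end - 60 + c(0, 30),
                          end_s = t_end - 60 + c(21, 51))
  wm <- last_minute_window(s$signal, straights = straights)
  expect_equal(wm$analyzed_duration, 42, tolerance = 0.05)
  pu_all <- detect_pushes(last_minute_window(s$signal))
  pu_masked <- detect_pushes(wm)
  expect_lt(nrow(pu_masked), nrow(pu_all))
  # every retained push lies fully inside a straight
  for (i in seq_len(nrow(pu_masked))) {
    ts <- wm$time[pu_masked$start[i]]; te <- wm$time[pu_masked$end[i]]
    expect_true(any(ts >= straights$start_s & te <= straights$end_s))
  }
})

test_that("noisy sessions recover ground truth within 5% over seeds", {
  errs <- NULL
  for (seed in 1:10) {
    p <- session_params(block_duration = 90, neg_work_per_cycle = -1.44,
                        rng_seed = seed)
    s <- generate_wheel_session(p)
    filt <- lowpass_filter(last_minute_window(s$signal))
    bm <- block_metrics(filt, detect_pushes(filt))
    tr <- s$truth
    errs <- rbind(errs, c(
      push_time = (bm$push_time - tr$push_time) / tr$push_time,
      cycle_time = (bm$cycle_time - tr$cycle_time) / tr$cycle_time,
      contact_angle = (bm$contact_angle - tr$contact_angle) / tr$contact_angle,
      work = (bm$work_per_push - tr$work_per_push) / tr$work_per_push,
      fef = (bm$fef - tr$fef) / tr$fef,
      power = (bm$power_output - tr$power_output) / tr$power_output))
  }
  expect_true(all(abs(colMeans(errs)) < 0.05))
})
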