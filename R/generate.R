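#' Generate a synthetic instrumented-wheel session
#'
#' Builds one block of handrim propulsion as it would be recorded by a
#' force/torque measurement wheel: cumulative wheel angle, three force
#' components and axle torque on a uniform time grid, plus the closed-form
#' per-push ground truth implied by the parameters.
#'
#' The push torque template spans the push phase with height `peak_torque`
#' (half-sine by default, see [session_params()]); braking is a short negative
#' half-sine right after hand release scaled so its work per cycle equals
#' `neg_work_per_cycle`. Total force magnitude is set so the push-averaged
#' effective-to-total force ratio equals `fef_target` exactly: the tangential
#' component is `torque / rim_radius` and the out-of-plane remainder is split
#' evenly over the two remaining axes. Additive iid Gaussian noise is applied
#' per force channel and to torque; the angle channel is noise-free
#' (encoder-like).
#'
#' Pushes that would not complete before the end of the block are omitted, so
#' the signal contains exactly the pushes listed in the ground truth.
#'
#' @param params a [session_params()] object.
#' @return A list with components
#'   \describe{
#'     \item{signal}{a `wheel_signal` object (see [wheel_signal()]).}
#'     \item{truth}{a `ground_truth` list: `n_pushes`, `push_time`,
#'       `cycle_time`, `contact_angle` (deg), `mean_torque`, `max_torque`
#'       (Nm), `work_per_push`, `negative_work_per_cycle` (J),
#'       `power_output` (W), `fef` (%), `speed` (m/s).}
#'   }
#' @examples
#' s <- generate_wheel_session(session_params(block_duration = 10,
#'                                            noise_sd_force = 0,
#'                                            noise_sd_torque = 0))
#' s$truth$n_pushes
#' @export
generate_wheel_session <- function(params) {
  stopifnot(inherits(params, "session_params"))
  validate_session_params(params)
  p <- params
  fs <- p$sample_rate
  n <- floor(p$block_duration * fs) + 1L
  t <- (seq_len(n) - 1L) / fs

  ca <- p$contact_angle * pi / 180               # contact angle, rad
  cyc_angle <- p$target_speed / p$wheel_radius * p$cycle_time
  omega_push <- ca / p$push_time
  omega_rec <- (cyc_angle - ca) / (p$cycle_time - p$push_time)

  truth <- push_ground_truth(p, ca, omega_push, omega_rec)

  u <- t - p$start_offset
  k <- floor(u / p$cycle_time)                   # cycle index per sample
  phase <- u - k * p$cycle_time

  # cumulative wheel angle (piecewise-linear in time, continuous)
  within <- ifelse(phase < p$push_time,
                   omega_push * phase,
                   ca + omega_rec * (phase - p$push_time))
  angle <- k * cyc_angle + within

  # push torque template over the normalized push phase
  tpl <- push_template(p)
  uu <- pmin(pmax(phase / p$push_time, 0), 1)
  torque <- ifelse(phase < p$push_time & phase > 0,
                   p$peak_torque * tpl$f(uu), 0)
  # braking burst after release, scaled to the requested work per cycle
  if (p$neg_work_per_cycle < 0) {
    peak_brake <- p$neg_work_per_cycle * pi / (2 * omega_rec * p$brake_time)
    bphase <- phase - p$push_time
    brake <- bphase > 0 & bphase < p$brake_time
    torque[brake] <- peak_brake * sin(pi * bphase[brake] / p$brake_time)
  }
  torque[k < 0 | k >= truth$n_pushes] <- 0       # drop incomplete pushes

  f <- p$fef_target / 100
  f_tan <- torque / p$rim_radius
  resid <- abs(f_tan) * sqrt(1 / f^2 - 1)
  fx <- f_tan
  fy <- resid / sqrt(2)
  fz <- resid / sqrt(2)

  set.seed(p$rng_seed)
  if (p$noise_sd_force > 0) {
    fx <- fx + stats::rnorm(n, 0, p$noise_sd_force)
    fy <- fy + stats::rnorm(n, 0, p$noise_sd_force)
    fz <- fz + stats::rnorm(n, 0, p$noise_sd_force)
  }
  if (p$noise_sd_torque > 0) {
    torque <- torque + stats::rnorm(n, 0, p$noise_sd_torque)
  }

  sig <- wheel_signal(time = t, angle = angle, fx = fx, fy = fy, fz = fz,
                      torque = torque, sample_rate = fs,
                      wheel_radius = p$wheel_radius,
                      rim_radius = p$rim_radius)
  list(signal = sig, truth = truth)
}

# normalized push torque template and its closed-form mean
# halfsine: f(u) = sin(pi u), mean 2/pi
# skewed:   f(u) = u^a (1-u)^b / mode height, mean B(a+1, b+1) / mode height
push_template <- function(p) {
  if (identical(p$push_shape, "skewed")) {
    a <- p$shape_rise; b <- p$shape_fall
    um <- a / (a + b)
    h <- um^a * (1 - um)^b
    list(f = function(u) u^a * (1 - u)^b / h,
         mean_frac = beta(a + 1, b + 1) / h)
  } else {
    list(f = function(u) sin(pi * u), mean_frac = 2 / pi)
  }
}

# closed-form per-push values implied by the session parameters
push_ground_truth <- function(p, ca, omega_push, omega_rec) {
  mean_torque <- push_template(p)$mean_frac * p$peak_torque
  work <- mean_torque * ca                       # int T dtheta over the push
  n_pushes <- floor((p$block_duration - p$start_offset - p$push_time) /
                      p$cycle_time) + 1L
  structure(list(
    n_pushes = as.integer(n_pushes),
    push_time = p$push_time,
    cycle_time = p$cycle_time,
    contact_angle = p$contact_angle,
    mean_torque = mean_torque,
    max_torque = p$peak_torque,
    work_per_push = work,
    negative_work_per_cycle = p$neg_work_per_cycle,
    power_output = (work + p$neg_work_per_cycle) / p$cycle_time,
    fef = p$fef_target,
    speed = p$target_speed
  ), class = "ground_truth")
}

#' Raw instrumented-wheel time series
#'
#' Container for the channels recorded by a measurement wheel on a uniform
#' time grid: cumulative rotation angle (propulsion positive), three force
#' components and axle torque (propulsive positive).
#'
#' @param time time stamps in s (strictly increasing, uniform).
#' @param angle cumulative wheel angle in rad.
#' @param fx,fy,fz force components in N.
#' @param torque axle torque in Nm.
#' @param sample_rate sampling frequency in Hz.
#' @param wheel_radius,rim_radius wheel and handrim radii in m.
#' @param filtered logical; set by [lowpass_filter()].
#' @return An object of class `wheel_signal`.
#' @export
wheel_signal <- function(time, angle, fx, fy, fz, torque, sample_rate,
                         wheel_radius, rim_radius, filtered = FALSE) {
  n <- length(time)
  if (n < 2L) stop("wheel_signal needs at least 2 samples", call. = FALSE)
  lens <- c(length(angle), length(fx), length(fy), length(fz), length(torque))
  if (any(lens != n)) {
    stop("all wheel_signal channels must have equal length", call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0) || max(abs(dt - 1 / sample_rate)) > 1e-6) {
    stop("time must be strictly increasing and uniform at sample_rate",
         call. = FALSE)
  }
  structure(list(time = time, angle = angle, fx = fx, fy = fy, fz = fz,
                 torque = torque, sample_rate = sample_rate,
                 wheel_radius = wheel_radius, rim_radius = rim_radius,
                 filtered = filtered),
            class = "wheel_signal")
}

#' @export
print.wheel_signal <- function(x, ...) {
  cat(sprintf(
    "Wheel signal: %d samples @ %g Hz (%.1f s)%s\n",
    length(x$time), x$sample_rate, diff(range(x$time)),
    if (isTRUE(x$filtered)) ", low-pass filtered" else ""))
  cat(sprintf("  wheel r = %g m, rim r = %g m; torque range [%.2f, %.2f] Nm\n",
              x$wheel_radius, x$rim_radius, min(x$torque), max(x$torque)))
  invisible(x)
}

#' @export
as.data.frame.wheel_signal <- function(x, ...) {
  data.frame(time_s = x$time, angle_rad = x$angle, fx_N = x$fx, fy_N = x$fy,
             fz_N = x$fz, torque_Nm = x$torque)
}

#' @export
plot.wheel_signal <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$torque, type = "l", xlab = "time (s)",
                 ylab = "torque (Nm)", ...)
  graphics::plot(x$time, sqrt(x$fx^2 + x$fy^2 + x$fz^2), type = "l",
                 xlab = "time (s)", ylab = "total force (N)", ...)
  invisible(x)
}

#' Generate a back-and-forth coast-down test
#'
#' Simulates the deceleration of a freely rolling wheelchair in both
#' directions of travel under constant rolling friction, optionally with a
#' constant slope-induced bias that aids one direction and opposes the other,
#' plus Gaussian measurement noise on velocity.
#'
#' @param mass system mass in kg (> 0).
#' @param friction_coefficient dimensionless rolling-friction coefficient.
#' @param initial_speed release speed in m/s (> 0).
#' @param slope_bias extra deceleration in one direction (m/s^2), subtracted
#'   in the other; models a slightly sloped floor.
#' @param noise_sd velocity measurement noise SD in m/s.
#' @param sample_rate velocity sampling rate in Hz.
#' @param rng_seed integer seed.
#' @return An object of class `coastdown_pair`: a list of two data frames
#'   (`forward`, `backward`) with columns `time_s`, `velocity_ms`,
#'   `direction`, truncated before the true velocity reaches zero.
#' @export
generate_coastdown <- function(mass, friction_coefficient,
                               initial_speed = 2.0, slope_bias = 0,
                               noise_sd = 0, sample_rate = 100,
                               rng_seed = 1L) {
  if (!is.numeric(mass) || mass <= 0) {
    stop("invalid coast-down parameter `mass`: must be positive",
         call. = FALSE)
  }
  if (!is.numeric(initial_speed) || initial_speed <= 0) {
    stop("invalid coast-down parameter `initial_speed`: must be positive",
         call. = FALSE)
  }
  g <- 9.81
  set.seed(rng_seed)
  one <- function(decel, direction) {
    if (decel <= 0) {
      stop("coast-down not decelerating: |slope_bias| exceeds friction",
           call. = FALSE)
    }
    t_end <- 0.95 * initial_speed / decel     # stop before v reaches 0
    t <- seq(0, t_end, by = 1 / sample_rate)
    v <- initial_speed - decel * t
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    data.frame(time_s = t, velocity_ms = v, direction = direction)
  }
  out <- list(forward = one(friction_coefficient * g + slope_bias, "forward"),
              backward = one(friction_coefficient * g - slope_bias, "backward"))
  class(out) <- "coastdown_pair"
  out
}

#' Generate breath-by-breath gas-exchange and heart-rate data
#'
#' Mono-exponential onset from rest toward steady state for oxygen uptake and
#' heart rate, with a constant respiratory exchange ratio and iid breath-to-
#' breath noise. Over a window much longer than `tau` the last-minute mean
#' approaches the steady-state targets.
#'
#' @param vo2_ss steady-state oxygen uptake in L/min.
#' @param rer_ss steady-state respiratory exchange ratio (VCO2/VO2).
#' @param hr_ss steady-state heart rate in bpm.
#' @param tau onset time constant in s.
#' @param duration series length in s.
#' @param breath_interval mean time between breaths in s.
#' @param vo2_rest,hr_rest resting values the onset starts from.
#' @param noise_sd_vo2,noise_sd_hr breath-to-breath noise SDs.
#' @param rng_seed integer seed.
#' @return An object of class `breath_series`: a data frame with columns
#'   `time_s`, `vo2_Lmin`, `vco2_Lmin`, `rer`, `hr_bpm`.
#' @export
generate_breath_data <- function(vo2_ss, rer_ss = 0.9, hr_ss = 95,
                                 tau = 30, duration = 240,
                                 breath_interval = 3,
                                 vo2_rest = 0.3, hr_rest = 70,
                                 noise_sd_vo2 = 0, noise_sd_hr = 0,
                                 rng_seed = 1L) {
  if (!is.numeric(tau) || tau <= 0) {
    stop("invalid breath parameter `tau`: must be positive", call. = FALSE)
  }
  if (rer_ss < 0.6 || rer_ss > 1.3) {
    warning("rer_ss outside the typical physiological range [0.7, 1.3]")
  }
  set.seed(rng_seed)
  t <- seq(0, duration, by = breath_interval)
  onset <- 1 - exp(-t / tau)
  vo2 <- vo2_rest + (vo2_ss - vo2_rest) * onset
  hr <- hr_rest + (hr_ss - hr_rest) * onset
  if (noise_sd_vo2 > 0) vo2 <- pmax(0.01, vo2 + stats::rnorm(length(t), 0, noise_sd_vo2))
  if (noise_sd_hr > 0) hr <- hr + stats::rnorm(length(t), 0, noise_sd_hr)
  out <- data.frame(time_s = t, vo2_Lmin = vo2, vco2_Lmin = rer_ss * vo2,
                    rer = rer_ss, hr_bpm = hr)
  class(out) <- c("breath_series", "data.frame")
  out
}
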