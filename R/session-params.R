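#' Parameters for a simulated propulsion session
#'
#' Bundles everything the generator needs to synthesize one block of handrim
#' propulsion on an instrumented wheel: geometry, cadence, torque template,
#' force-effectiveness target, measurement noise and the random seed.
#'
#' The kinematic profile is prescribed, not dynamic: the wheel turns at a
#' constant angular velocity during the push (set by `contact_angle` over
#' `push_time`) and at a second constant angular velocity during recovery,
#' chosen so the block-average forward speed equals `target_speed`.
#'
#' @param n_participants number of participants a study-level caller intends
#'   to simulate with these settings (carried along, not used by the
#'   single-session generator).
#' @param modality one of `"OG"` (overground), `"TM"` (treadmill),
#'   `"WE"` (ergometer). A label only; the signal model is shared.
#' @param block_duration block length in seconds.
#' @param sample_rate sampling frequency of the measurement wheel in Hz.
#' @param wheel_radius,rim_radius wheel and handrim radii in m
#'   (`rim_radius < wheel_radius`).
#' @param system_mass combined user + wheelchair mass in kg.
#' @param friction_coefficient dimensionless rolling-friction coefficient.
#' @param target_speed mean forward speed in m/s.
#' @param push_time hand-contact duration per push in s.
#' @param cycle_time time between consecutive push starts in s.
#' @param contact_angle wheel rotation per push in degrees.
#' @param fef_target push-averaged fraction of effective force in percent,
#'   in (0, 100].
#' @param peak_torque peak of the push torque template in Nm.
#' @param push_shape torque template over the normalized push phase
#'   `u = t/push_time`: `"halfsine"` (`sin(pi u)`, the default) or
#'   `"skewed"` (`u^a (1-u)^b` scaled to peak at `peak_torque`), whose
#'   rise exponent `a > 1` delays the torque build-up within the push — the
#'   shape feature that distinguishes treadmill propulsion. Both have
#'   closed-form means (`2/pi`, and `B(a+1, b+1)` over the mode height).
#' @param shape_rise,shape_fall exponents `a`, `b` of the skewed template.
#' @param neg_work_per_cycle braking work per cycle in J (<= 0); realized as
#'   a short negative half-sine torque burst right after hand release.
#' @param brake_time duration of the braking burst in s.
#' @param noise_sd_force,noise_sd_torque additive iid Gaussian measurement
#'   noise SD per force channel (N) and on axle torque (Nm).
#' @param start_offset time of the first push onset in s. The default, half
#'   a sample period, aligns the push so that a push lasting a whole number
#'   of sample periods covers exactly that many strictly positive torque
#'   samples.
#' @param rng_seed integer seed; fixing it makes generation bit-reproducible.
#'
#' @return An object of class `session_params` (a validated list).
#' @seealso [generate_wheel_session()]
#' @export
session_params <- function(n_participants = 1L,
                           modality = c("OG", "TM", "WE"),
                           block_duration = 240,
                           sample_rate = 200,
                           wheel_radius = 0.30,
                           rim_radius = 0.27,
                           system_mass = 91.6,
                           friction_coefficient = 0.008,
                           target_speed = 1.11,
                           push_time = 0.35,
                           cycle_time = 1.43,
                           contact_angle = 71.43,
                           fef_target = 69.28,
                           peak_torque = 7.27,
                           push_shape = c("halfsine", "skewed"),
                           shape_rise = 2,
                           shape_fall = 1,
                           neg_work_per_cycle = -1.44,
                           brake_time = 0.12,
                           noise_sd_force = 1.0,
                           noise_sd_torque = 0.15,
                           start_offset = NULL,
                           rng_seed = 1L) {
  modality <- match.arg(modality)
  push_shape <- match.arg(push_shape)
  if (is.null(start_offset)) start_offset <- 0.5 / sample_rate
  p <- list(
    n_participants = as.integer(n_participants), modality = modality,
    block_duration = block_duration, sample_rate = sample_rate,
    wheel_radius = wheel_radius, rim_radius = rim_radius,
    system_mass = system_mass, friction_coefficient = friction_coefficient,
    target_speed = target_speed, push_time = push_time,
    cycle_time = cycle_time, contact_angle = contact_angle,
    fef_target = fef_target, peak_torque = peak_torque,
    push_shape = push_shape, shape_rise = shape_rise,
    shape_fall = shape_fall,
    neg_work_per_cycle = neg_work_per_cycle, brake_time = brake_time,
    noise_sd_force = noise_sd_force, noise_sd_torque = noise_sd_torque,
    start_offset = start_offset, rng_seed = as.integer(rng_seed)
  )
  class(p) <- "session_params"
  validate_session_params(p)
  p
}

#' @keywords internal
validate_session_params <- function(p) {
  fail <- function(field, why) {
    stop(sprintf("invalid session parameter `%s`: %s", field, why),
         call. = FALSE)
  }
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      fail(field, "must be a single finite number")
    }
    v
  }
  for (f in c("block_duration", "sample_rate", "wheel_radius", "rim_radius",
              "system_mass", "target_speed", "push_time", "cycle_time",
              "contact_angle", "fef_target", "peak_torque")) {
    if (num1(f) <= 0) fail(f, "must be positive")
  }
  num1("noise_sd_force"); num1("noise_sd_torque")
  num1("neg_work_per_cycle"); num1("brake_time")
  if (p$noise_sd_force < 0) fail("noise_sd_force", "must be >= 0")
  if (p$noise_sd_torque < 0) fail("noise_sd_torque", "must be >= 0")
  if (p$push_time >= p$cycle_time) {
    fail("push_time", "must be smaller than cycle_time")
  }
  if (p$fef_target > 100) fail("fef_target", "must lie in (0, 100]")
  if (p$rim_radius >= p$wheel_radius) {
    fail("rim_radius", "must be smaller than wheel_radius")
  }
  if (p$friction_coefficient < 0) {
    fail("friction_coefficient", "must be >= 0")
  }
  if (identical(p$push_shape, "skewed")) {
    if (num1("shape_rise") < 1) fail("shape_rise", "must be >= 1")
    if (num1("shape_fall") <= 0) fail("shape_fall", "must be positive")
  }
  if (p$neg_work_per_cycle > 0) {
    fail("neg_work_per_cycle", "must be <= 0 (braking work)")
  }
  if (p$brake_time <= 0 || p$brake_time >= p$cycle_time - p$push_time) {
    fail("brake_time", "must fit inside the recovery phase")
  }
  if (p$block_duration < 2 * p$cycle_time) {
    fail("block_duration", "must cover at least two cycles")
  }
  # recovery angular velocity must be non-negative for the speed target
  ca <- p$contact_angle * pi / 180
  cyc_angle <- p$target_speed / p$wheel_radius * p$cycle_time
  if (cyc_angle < ca) {
    fail("contact_angle",
         "exceeds the wheel rotation per cycle implied by target_speed")
  }
  invisible(p)
}

#' @export
print.session_params <- function(x, ...) {
  cat(sprintf("Propulsion session parameters [%s]\n", x$modality))
  cat(sprintf("  block %g s @ %g Hz, wheel r = %g m, rim r = %g m\n",
              x$block_duration, x$sample_rate, x$wheel_radius, x$rim_radius))
  cat(sprintf("  cadence: push %g s / cycle %g s, contact angle %g deg\n",
              x$push_time, x$cycle_time, x$contact_angle))
  cat(sprintf("  peak torque %g Nm, FEF target %g%%, speed %g m/s\n",
              x$peak_torque, x$fef_target, x$target_speed))
  cat(sprintf("  noise: force %g N, torque %g Nm (seed %d)\n",
              x$noise_sd_force, x$noise_sd_torque, x$rng_seed))
  invisible(x)
}
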