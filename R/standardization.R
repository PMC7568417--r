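#' Estimate rolling resistance from a back-and-forth coast-down test
#'
#' Fits a straight line to each decelerating velocity trace and converts the
#' mean absolute slope to a constant rolling-friction force. Averaging the
#' two travel directions cancels any constant slope-induced bias exactly:
#' a tilt of the floor adds `+b` to one deceleration and `-b` to the other.
#' Friction is modeled as constant and independent of velocity, so the fit
#' is linear (no air-drag quadratic term) and the deceleration model uses
#' translational mass only.
#'
#' @param traces a `coastdown_pair` from [generate_coastdown()], or any list
#'   of two data frames with columns `time_s`, `velocity_ms`.
#' @param system_mass combined user + wheelchair mass in kg.
#' @param g gravitational acceleration, m/s^2.
#' @return An object of class `resistance_profile`: `friction_force` (N),
#'   `friction_coefficient`, `system_mass` (kg), `slopes` (m/s^2, per
#'   direction), `g`.
#' @export
fit_coastdown <- function(traces, system_mass, g = 9.81) {
  stopifnot(length(traces) == 2L, system_mass > 0)
  slope <- vapply(traces, function(tr) {
    if (nrow(tr) < 10L) {
      stop("coast-down trace needs at least 10 samples", call. = FALSE)
    }
    unname(stats::coef(stats::lm(velocity_ms ~ time_s, data = tr))[2L])
  }, numeric(1))
  if (all(slope >= 0)) {
    stop("coast-down traces are not decelerating in either direction",
         call. = FALSE)
  }
  friction <- system_mass * mean(abs(slope))
  structure(list(friction_force = friction,
                 friction_coefficient = friction / (system_mass * g),
                 system_mass = system_mass,
                 slopes = slope, g = g),
            class = "resistance_profile")
}

#' @export
print.resistance_profile <- function(x, ...) {
  cat(sprintf("Rolling resistance: %.3f N (mu = %.5f, m = %.1f kg)\n",
              x$friction_force, x$friction_coefficient, x$system_mass))
  cat(sprintf("  coast-down slopes: %.4f / %.4f m/s^2\n",
              x$slopes[1L], x$slopes[2L]))
  invisible(x)
}

#' Standardized target power at a given speed
#'
#' Under constant rolling friction the external power needed to hold a
#' steady speed is simply friction force times speed.
#'
#' @param profile a `resistance_profile`.
#' @param speed propulsion speed in m/s (> 0 for a propulsion target;
#'   0 yields 0 W).
#' @return Power in W.
#' @export
target_power <- function(profile, speed) {
  stopifnot(inherits(profile, "resistance_profile"), speed >= 0)
  profile$friction_force * speed
}

#' Pulley mass matching treadmill power to the overground reference
#'
#' On a treadmill the rolling resistance (measured with a drag test) is
#' usually lower than overground; a pulley pulling the wheelchair backward
#' with weight `pulley_mass * g` makes up the difference. If the treadmill
#' drag already exceeds the overground friction the pulley cannot help and
#' the mass is clamped to zero with a warning.
#'
#' @param profile a `resistance_profile` (overground reference).
#' @param drag_force treadmill drag-test force in N (>= 0).
#' @return Pulley mass in kg.
#' @export
match_treadmill <- function(profile, drag_force) {
  stopifnot(inherits(profile, "resistance_profile"), drag_force >= 0)
  m <- (profile$friction_force - drag_force) / profile$g
  if (m < 0) {
    warning("treadmill drag exceeds overground friction; pulley mass clamped to 0")
    m <- 0
  }
  m
}

#' Ergometer configuration reproducing the overground resistance
#'
#' A roller ergometer simulates rolling friction in software; setting its
#' friction coefficient to the coast-down estimate and its simulated inertia
#' to the real system mass reproduces the overground power requirement.
#'
#' @param profile a `resistance_profile`.
#' @return A list with `mu` (simulated friction coefficient) and
#'   `simulated_mass` (kg).
#' @export
set_ergometer <- function(profile) {
  stopifnot(inherits(profile, "resistance_profile"))
  list(mu = profile$friction_coefficient,
       simulated_mass = profile$system_mass)
}
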