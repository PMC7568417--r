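#' Detect pushes in a wheel signal
#'
#' Segments the torque channel into pushes. Candidate regions are maximal
#' runs of strictly positive torque that reach `threshold` somewhere inside
#' (a hysteresis-like rule: small positive noise runs never reach the
#' threshold and are discarded, while a push is traced out to the zero
#' crossings on either side, so its duration does not depend on the
#' threshold). Candidates starting closer together than `min_cycle_time` are
#' merged; candidates shorter than `min_push_time`, and candidates touching
#' the first or last sample (necessarily truncated), are dropped. Boundary
#' samples below `boundary_trim_frac` of the push's peak torque are trimmed
#' off: a zero-phase low-pass filter leaks a few near-zero samples beyond
#' the true contact interval, and the trim removes that baseline leakage
#' without touching genuine push samples.
#'
#' Per push, with half-open sample interval `[start, end)`:
#' contact angle is `angle[end] - angle[start]` in degrees; work is the
#' integral of torque over angle across the push, discretized as
#' `sum(torque[i] * (angle[i+1] - angle[i]))` over the half-open interval
#' (the midpoint rule on this grid), which makes the constant-torque
#' identity `work = mean_torque * contact_angle` exact; the fraction
#' of effective force (FEF) compares the tangential force `torque/rim_radius`
#' with the total force magnitude `sqrt(fx^2+fy^2+fz^2)`, by default as a
#' ratio of push means (`"ratio_of_means"`), optionally as the push mean of
#' pointwise ratios (`"mean_of_ratios"`).
#'
#' If the signal carries a straight-segment mask (see
#' [last_minute_window()]), pushes overlapping masked-out samples are
#' excluded.
#'
#' @param signal a (typically low-pass filtered) `wheel_signal`.
#' @param threshold torque a candidate region must reach, in Nm.
#' @param min_push_time minimum push duration in s.
#' @param min_cycle_time minimum separation of push starts in s.
#' @param boundary_trim_frac boundary samples below this fraction of the
#'   push peak are trimmed.
#' @param fef_mode how FEF is aggregated within a push.
#' @return A data frame of class `push_table`, one row per push, with
#'   columns `start`, `end` (1-based, half-open), `t_start`, `push_time`,
#'   `cycle_time` (NA for the last push), `contact_angle` (deg),
#'   `mean_torque`, `max_torque` (Nm), `work` (J), `fef` (%). An empty
#'   signal is an error; a signal with no pushes yields zero rows.
#' @export
detect_pushes <- function(signal, threshold = 1, min_push_time = 0.1,
                          min_cycle_time = 0.3, boundary_trim_frac = 0.02,
                          fef_mode = c("ratio_of_means", "mean_of_ratios")) {
  stopifnot(inherits(signal, "wheel_signal"))
  fef_mode <- match.arg(fef_mode)
  tq <- signal$torque
  n <- length(tq)
  if (n == 0L) stop("empty signal", call. = FALSE)
  fs <- signal$sample_rate

  pos <- tq > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]           # inclusive runs
  if (length(starts)) {
    reach <- vapply(seq_along(starts), function(i) {
      max(tq[starts[i]:ends[i]]) >= threshold
    }, logical(1))
    starts <- starts[reach]; ends <- ends[reach]
  }
  # merge candidates whose onsets are closer than min_cycle_time
  if (length(starts) > 1L) {
    m_start <- starts[1L]; m_end <- ends[1L]
    out_s <- integer(0); out_e <- integer(0)
    for (i in 2L:length(starts)) {
      if ((starts[i] - m_start) / fs < min_cycle_time) {
        m_end <- ends[i]
      } else {
        out_s <- c(out_s, m_start); out_e <- c(out_e, m_end)
        m_start <- starts[i]; m_end <- ends[i]
      }
    }
    starts <- c(out_s, m_start); ends <- c(out_e, m_end)
  }
  if (length(starts) && boundary_trim_frac > 0) {
    for (i in seq_along(starts)) {
      floor_i <- boundary_trim_frac * max(tq[starts[i]:ends[i]])
      while (starts[i] < ends[i] && tq[starts[i]] < floor_i) {
        starts[i] <- starts[i] + 1L
      }
      while (ends[i] > starts[i] && tq[ends[i]] < floor_i) {
        ends[i] <- ends[i] - 1L
      }
    }
  }
  if (length(starts)) {
    dur_ok <- (ends - starts + 1L) / fs >= min_push_time
    interior <- starts > 1L & ends < n
    starts <- starts[dur_ok & interior]; ends <- ends[dur_ok & interior]
  }
  if (!is.null(signal$mask) && length(starts)) {
    ok <- vapply(seq_along(starts), function(i) {
      all(signal$mask[starts[i]:(ends[i] + 1L)])
    }, logical(1))
    starts <- starts[ok]; ends <- ends[ok]
  }

  k <- length(starts)
  if (k == 0L) {
    out <- data.frame(start = integer(0), end = integer(0),
                      t_start = numeric(0), push_time = numeric(0),
                      cycle_time = numeric(0), contact_angle = numeric(0),
                      mean_torque = numeric(0), max_torque = numeric(0),
                      work = numeric(0), fef = numeric(0))
    class(out) <- c("push_table", "data.frame")
    return(out)
  }

  end_ho <- ends + 1L                                  # half-open end index
  ftot <- sqrt(signal$fx^2 + signal$fy^2 + signal$fz^2)
  rows <- lapply(seq_len(k), function(i) {
    s <- starts[i]; e <- end_ho[i]
    idx <- s:(e - 1L)
    eff <- signal$torque[idx] / signal$rim_radius
    fef <- switch(fef_mode,
                  ratio_of_means = 100 * mean(eff) / mean(ftot[idx]),
                  mean_of_ratios = mean(100 * eff / ftot[idx]))
    data.frame(
      start = s, end = e,
      t_start = signal$time[s],
      push_time = (e - s) / fs,
      cycle_time = NA_real_,
      contact_angle = (signal$angle[e] - signal$angle[s]) * 180 / pi,
      mean_torque = mean(signal$torque[idx]),
      max_torque = max(signal$torque[idx]),
      work = sum(signal$torque[idx] * diff(signal$angle[s:e])),
      fef = fef)
  })
  out <- do.call(rbind, rows)
  if (k > 1L) out$cycle_time[-k] <- diff(out$t_start)
  attr(out, "sample_rate") <- fs
  class(out) <- c("push_table", "data.frame")
  out
}

#' Per-block discrete outcomes
#'
#' Summarizes a detected [push_table][detect_pushes()] into the block-level
#' discrete outcomes: per-push means of push time, cycle time, contact
#' angle, mean/max torque, work and FEF, plus power output, mean speed and
#' negative work per cycle computed from the signal.
#'
#' Power output is the time average of `torque * omega` over the span from
#' the first to the last push start, i.e. over whole propulsion cycles; a
#' window cut mid-cycle would bias the average by a fraction of one push's
#' work. Speed is `wheel_radius` times the mean angular velocity over the
#' same span. Negative work per cycle integrates `min(torque * omega, 0)`
#' over each cycle and averages across cycles. Angular velocity comes from
#' central differences of the angle channel, passed through the same
#' low-pass filter as the kinetic channels when the signal was filtered.
#'
#' @param signal the `wheel_signal` the pushes were detected in.
#' @param pushes a `push_table`.
#' @return An object of class `block_metrics`: a list with elements
#'   `n_pushes`, `push_time`, `cycle_time`, `contact_angle`, `mean_torque`,
#'   `max_torque`, `work_per_push`, `fef`, `power_output`, `speed`,
#'   `negative_work_per_cycle`. With fewer than 2 pushes the cycle-based
#'   fields are `NA` and `cycle_metrics_defined` is `FALSE`.
#' @export
block_metrics <- function(signal, pushes) {
  stopifnot(inherits(signal, "wheel_signal"), inherits(pushes, "push_table"))
  k <- nrow(pushes)
  out <- list(
    n_pushes = as.numeric(k),
    push_time = if (k) mean(pushes$push_time) else NA_real_,
    cycle_time = if (k > 1L) mean(pushes$cycle_time, na.rm = TRUE) else NA_real_,
    contact_angle = if (k) mean(pushes$contact_angle) else NA_real_,
    mean_torque = if (k) mean(pushes$mean_torque) else NA_real_,
    max_torque = if (k) mean(pushes$max_torque) else NA_real_,
    work_per_push = if (k) mean(pushes$work) else NA_real_,
    fef = if (k) mean(pushes$fef) else NA_real_,
    power_output = NA_real_, speed = NA_real_,
    negative_work_per_cycle = NA_real_,
    cycle_metrics_defined = k >= 2L
  )
  if (k >= 2L) {
    fs <- signal$sample_rate
    omega <- angular_velocity(signal)
    i0 <- pushes$start[1L]; i1 <- pushes$start[k]
    span <- i0:i1
    tt <- signal$time[span]
    pw <- signal$torque[span] * omega[span]
    out$power_output <- trapz(tt, pw) / (tt[length(tt)] - tt[1L])
    out$speed <- signal$wheel_radius *
      (signal$angle[i1] - signal$angle[i0]) / (tt[length(tt)] - tt[1L])
    neg <- vapply(seq_len(k - 1L), function(j) {
      idx <- pushes$start[j]:pushes$start[j + 1L]
      trapz(signal$time[idx], pmin(signal$torque[idx] * omega[idx], 0))
    }, numeric(1))
    out$negative_work_per_cycle <- mean(neg)
  }
  class(out) <- "block_metrics"
  out
}

# central-difference angular velocity, low-pass matched to the signal
angular_velocity <- function(signal) {
  a <- signal$angle
  n <- length(a)
  fs <- signal$sample_rate
  omega <- numeric(n)
  omega[2:(n - 1L)] <- (a[3:n] - a[1:(n - 2L)]) * fs / 2
  omega[1L] <- (a[2L] - a[1L]) * fs
  omega[n] <- (a[n] - a[n - 1L]) * fs
  if (isTRUE(signal$filtered)) {
    fl <- signal$filter_spec
    if (is.null(fl)) fl <- list(cutoff = 10, order = 4)
    bf <- signal::butter(fl$order, 2 * fl$cutoff / fs, type = "low")
    omega <- filtfilt_padded(bf$b, bf$a, omega)
  }
  omega
}

#' @export
print.block_metrics <- function(x, ...) {
  cat("Block metrics:", x$n_pushes, "pushes\n")
  fmt <- function(v, u) if (is.na(v)) "NA" else sprintf("%.3f %s", v, u)
  cat("  push time      ", fmt(x$push_time, "s"),
      "  cycle time ", fmt(x$cycle_time, "s"), "\n")
  cat("  contact angle  ", fmt(x$contact_angle, "deg"),
      "  FEF        ", fmt(x$fef, "%"), "\n")
  cat("  mean torque    ", fmt(x$mean_torque, "Nm"),
      "  max torque ", fmt(x$max_torque, "Nm"), "\n")
  cat("  work per push  ", fmt(x$work_per_push, "J"),
      "  neg work   ", fmt(x$negative_work_per_cycle, "J"), "\n")
  cat("  power output   ", fmt(x$power_output, "W"),
      "  speed      ", fmt(x$speed, "m/s"), "\n")
  invisible(x)
}

#' Extract the steady-state analysis window
#'
#' Returns the final portion (default: last 60 s) of a block, the part of a
#' steady-state block conventionally analyzed. For overground blocks
#' recorded on a circuit, an optional table of straight-segment intervals
#' masks out corners: samples outside the straights are flagged and pushes
#' overlapping them are excluded by [detect_pushes()].
#'
#' @param signal a `wheel_signal`.
#' @param window window length in s (default 60).
#' @param straights optional data frame with columns `start_s`, `end_s`
#'   giving straight-segment intervals on the original time axis.
#' @return The sliced `wheel_signal`, with elements `mask` (logical, kept
#'   samples) and `analyzed_duration` (s) when `straights` is given.
#' @export
last_minute_window <- function(signal, window = 60, straights = NULL) {
  stopifnot(inherits(signal, "wheel_signal"))
  fs <- signal$sample_rate
  n <- length(signal$time)
  dur <- signal$time[n] - signal$time[1L]
  if (dur < window) {
    stop(sprintf("signal (%.1f s) is shorter than the analysis window (%g s)",
                 dur, window), call. = FALSE)
  }
  m <- round(window * fs)
  idx <- (n - m):n
  out <- signal
  for (ch in c("time", "angle", "fx", "fy", "fz", "torque")) {
    out[[ch]] <- signal[[ch]][idx]
  }
  if (!is.null(straights)) {
    tt <- out$time
    mask <- rep(FALSE, length(tt))
    for (i in seq_len(nrow(straights))) {
      mask <- mask | (tt >= straights$start_s[i] & tt <= straights$end_s[i])
    }
    out$mask <- mask
    out$analyzed_duration <- sum(mask) / fs
  } else {
    out$analyzed_duration <- window
  }
  out
}

# trapezoidal rule on a (not necessarily uniform) grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}
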