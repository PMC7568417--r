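#' Zero-phase low-pass filter for wheel signals
#'
#' Applies a forward-backward (zero-phase) Butterworth low-pass filter to the
#' force and torque channels of a [wheel_signal()]. The angle channel is left
#' untouched: it comes from an encoder and is integrated, so filtering it
#' would only distort push boundaries.
#'
#' The two passes square the magnitude response, so the nominal `order`
#' refers to the designed filter, applied once in each direction.
#'
#' @param signal a `wheel_signal`.
#' @param cutoff cut-off frequency in Hz; must be below the Nyquist
#'   frequency.
#' @param order Butterworth order of the designed filter.
#' @return The filtered `wheel_signal` (same length, `filtered = TRUE`).
#' @export
lowpass_filter <- function(signal, cutoff = 10, order = 4) {
  stopifnot(inherits(signal, "wheel_signal"))
  fs <- signal$sample_rate
  if (cutoff >= fs / 2) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff, fs / 2), call. = FALSE)
  }
  bf <- signal::butter(order, 2 * cutoff / fs, type = "low")
  for (ch in c("fx", "fy", "fz", "torque")) {
    signal[[ch]] <- filtfilt_padded(bf$b, bf$a, signal[[ch]])
  }
  signal$filtered <- TRUE
  signal
}

# Forward-backward IIR filtering with odd-reflection end padding and
# steady-state initial conditions: each pass starts as if the first sample
# had been applied forever, so no start-up transient enters the output.
filtfilt_padded <- function(b, a, x) {
  n <- length(x)
  np <- min(n - 1L, 3L * max(length(a), length(b)))
  pre <- 2 * x[1L] - x[seq(np + 1L, 2L, by = -1L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - np, by = -1L)]
  xp <- c(pre, x, post)
  dc <- sum(b) / sum(a)
  pass <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1L], length(b) - 1L),
                              init.y = rep(z[1L] * dc, length(a) - 1L)))
  }
  y <- pass(xp)
  y <- rev(pass(rev(y)))
  y[(np + 1L):(np + n)]
}
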