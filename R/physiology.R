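#' Energy expenditure from steady-state gas exchange
#'
#' Converts oxygen uptake to metabolic power with the oxygen energy
#' equivalent `4.94 * RER + 16.04` kJ per liter O2 (Garby-Astrup), averaged
#' over the final `window` seconds of the series:
#' `EE(W) = VO2(L/min) * (4940 * RER + 16040) / 60`.
#'
#' @param breaths a [breath_series][generate_breath_data()] (data frame with
#'   `time_s`, `vo2_Lmin`, `rer`).
#' @param window averaging window at the end of the series, in s.
#' @param kj_per_l_intercept,kj_per_l_rer coefficients of the energy
#'   equivalent in kJ/L, `intercept + slope * RER`.
#' @return Energy expenditure in W. A mean RER outside [0.7, 1.0] triggers a
#'   warning (protein/anaerobic contributions outside the model's validity)
#'   but the value is still returned.
#' @export
energy_expenditure <- function(breaths, window = 60,
                               kj_per_l_intercept = 16.04,
                               kj_per_l_rer = 4.94) {
  w <- tail_window(breaths, window)
  vo2 <- mean(w$vo2_Lmin, na.rm = TRUE)
  rer <- mean(w$rer, na.rm = TRUE)
  if (!is.na(rer) && (rer < 0.7 || rer > 1.0)) {
    warning(sprintf("mean RER %.2f outside [0.7, 1.0]; energy equivalent extrapolated", rer))
  }
  vo2 * (kj_per_l_rer * rer + kj_per_l_intercept) * 1000 / 60
}

#' Gross mechanical efficiency
#'
#' External power output as a percentage of metabolic energy expenditure.
#'
#' @param power_output external power in W.
#' @param ee energy expenditure in W (> 0).
#' @return Efficiency in percent.
#' @export
gross_mechanical_efficiency <- function(power_output, ee) {
  if (!is.finite(ee) || ee <= 0) {
    stop("energy expenditure must be positive", call. = FALSE)
  }
  100 * power_output / ee
}

#' Mean heart rate over the analysis window
#'
#' Missing-aware mean of the heart-rate channel over the final `window`
#' seconds. Participants without any heart-rate signal are reported as
#' missing (`NA`), never as zero, so they can be excluded listwise at the
#' cohort level.
#'
#' @param breaths a breath series (data frame with `time_s`, `hr_bpm`).
#' @param window averaging window in s.
#' @return Mean heart rate in bpm, or `NA` if no valid sample exists.
#' @export
mean_heart_rate <- function(breaths, window = 60) {
  w <- tail_window(breaths, window)
  hr <- w$hr_bpm
  if (all(is.na(hr))) return(NA_real_)
  mean(hr, na.rm = TRUE)
}

tail_window <- function(breaths, window) {
  stopifnot(is.data.frame(breaths), nrow(breaths) > 0L)
  t_end <- max(breaths$time_s)
  breaths[breaths$time_s > t_end - window, , drop = FALSE]
}
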