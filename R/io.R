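#' Write and read wheel sessions, coast-down traces and breath series
#'
#' Plain-text interchange for all generated data. Wheel sessions are CSV
#' with columns `time_s, angle_rad, fx_N, fy_N, fz_N, torque_Nm` plus a JSON
#' sidecar carrying the session parameters and ground truth; breath series
#' are CSV with `time_s, vo2_Lmin, vco2_Lmin, rer, hr_bpm`; coast-down
#' traces are CSV with `time_s, velocity_ms, direction`.
#'
#' @param session a list with `signal` and `truth` as returned by
#'   [generate_wheel_session()].
#' @param params the [session_params()] used (stored in the sidecar).
#' @param csv_path,json_path output paths.
#' @return `csv_path`, invisibly.
#' @name session_io
#' @export
write_wheel_session <- function(session, params, csv_path,
                                json_path = sub("\\.csv$", ".json", csv_path)) {
  utils::write.csv(as.data.frame(session$signal), csv_path,
                   row.names = FALSE)
  side <- list(
    params = unclass(params),
    truth = unclass(session$truth),
    sample_rate = session$signal$sample_rate,
    wheel_radius = session$signal$wheel_radius,
    rim_radius = session$signal$rim_radius
  )
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname session_io
#' @param csv_path,json_path paths written by [write_wheel_session()].
#' @return For `read_wheel_session()`: a list with `signal` (a
#'   `wheel_signal`), `truth` and `params` (plain lists from the sidecar).
#' @export
read_wheel_session <- function(csv_path,
                               json_path = sub("\\.csv$", ".json", csv_path)) {
  df <- utils::read.csv(csv_path)
  need <- c("time_s", "angle_rad", "fx_N", "fy_N", "fz_N", "torque_Nm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("malformed wheel-session file %s: missing column(s) %s",
                 csv_path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  sig <- wheel_signal(time = df$time_s, angle = df$angle_rad, fx = df$fx_N,
                      fy = df$fy_N, fz = df$fz_N, torque = df$torque_Nm,
                      sample_rate = side$sample_rate,
                      wheel_radius = side$wheel_radius,
                      rim_radius = side$rim_radius)
  list(signal = sig, truth = side$truth, params = side$params)
}

#' @rdname session_io
#' @param traces a `coastdown_pair`.
#' @param path output CSV path.
#' @export
write_coastdown <- function(traces, path) {
  df <- rbind(traces[[1L]], traces[[2L]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_coastdown <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "velocity_ms", "direction")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("malformed coast-down file %s: missing column(s) %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- split(df, df$direction)
  class(out) <- "coastdown_pair"
  out
}

#' @rdname session_io
#' @param breaths a `breath_series`.
#' @export
write_breath_series <- function(breaths, path) {
  utils::write.csv(as.data.frame(breaths), path, row.names = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_breath_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "vo2_Lmin", "vco2_Lmin", "rer", "hr_bpm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("malformed breath-series file %s: missing column(s) %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  class(df) <- c("breath_series", "data.frame")
  df
}

#' Read a study configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [study_config()]
#' (unknown keys are an error, so typos fail loudly) and returns a
#' validated configuration.
#'
#' @param path YAML file path.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown study-config key(s) in %s: %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(study_config, raw)
}
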