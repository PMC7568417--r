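#' Study configuration for a three-modality propulsion cohort
#'
#' Describes a simulated cohort study comparing overground (OG), treadmill
#' (TM) and ergometer (WE) handrim propulsion at standardized speed and
#' power: cohort size, per-modality condition targets, block structure,
#' analysis window and statistical options. The per-modality defaults are
#' the group means and SDs of the study conditions this package emulates
#' (see `modality_defaults()`); the treadmill condition uses a rise-skewed
#' torque template (lower torque early in the push phase), the reported
#' qualitative signature of treadmill propulsion.
#'
#' Between-subject variation is drawn per variable with a participant
#' random effect shared across modalities (fraction `shared_variance_frac`
#' of the variance), which is what makes cross-modality agreement (ICC)
#' realistic rather than zero.
#'
#' @param n_participants cohort size.
#' @param modalities which conditions to simulate (2 or 3 of
#'   `"OG"`, `"TM"`, `"WE"`).
#' @param blocks propulsion blocks per modality.
#' @param block_duration block length in s.
#' @param sample_rate wheel sampling rate in Hz.
#' @param analysis_window steady-state window analyzed at the end of each
#'   block, in s.
#' @param wheel_radius,rim_radius wheel geometry in m.
#' @param system_mass user + wheelchair mass in kg.
#' @param shared_variance_frac fraction of between-subject variance shared
#'   across modalities (drives the population ICC).
#' @param n_hr_missing number of participants without heart-rate data
#'   (missing-data support; they are excluded listwise for heart rate only).
#' @param alpha significance level for all tests.
#' @param normality_alpha level of the Shapiro-Wilk screen.
#' @param Q nodes of the normalized push phase for SPM.
#' @param n_last_pushes pushes entering the continuous analysis.
#' @param noise_sd_force,noise_sd_torque wheel measurement noise.
#' @param noise_sd_vo2,noise_sd_hr breath-to-breath noise.
#' @param modality_overrides named list overriding entries of
#'   `modality_defaults()`, e.g.
#'   `list(TM = list(shape_rise = 3))`.
#' @param rng_seed integer master seed; every stochastic stage derives its
#'   seed from it, so a fixed seed makes the whole study reproducible.
#' @return A `study_config` object.
#' @export
study_config <- function(n_participants = 17L,
                         modalities = c("OG", "TM", "WE"),
                         blocks = 3L,
                         block_duration = 240,
                         sample_rate = 200,
                         analysis_window = 60,
                         wheel_radius = 0.30,
                         rim_radius = 0.27,
                         system_mass = 91.6,
                         shared_variance_frac = 0.8,
                         n_hr_missing = 3L,
                         alpha = 0.05,
                         normality_alpha = 0.05,
                         Q = 101L,
                         n_last_pushes = 20L,
                         noise_sd_force = 1.0,
                         noise_sd_torque = 0.15,
                         noise_sd_vo2 = 0.05,
                         noise_sd_hr = 2,
                         modality_overrides = NULL,
                         rng_seed = 1L) {
  modalities <- match.arg(modalities, c("OG", "TM", "WE"),
                          several.ok = TRUE)
  if (length(modalities) < 2L) {
    stop("a comparison study needs at least 2 modalities", call. = FALSE)
  }
  if (n_participants < 3L) stop("need at least 3 participants", call. = FALSE)
  if (block_duration < analysis_window) {
    stop("block_duration must cover the analysis window", call. = FALSE)
  }
  cond <- modality_defaults()
  if (!is.null(modality_overrides)) {
    for (m in names(modality_overrides)) {
      cond[[m]][names(modality_overrides[[m]])] <- modality_overrides[[m]]
    }
  }
  cfg <- list(
    n_participants = as.integer(n_participants), modalities = modalities,
    blocks = as.integer(blocks), block_duration = block_duration,
    sample_rate = sample_rate, analysis_window = analysis_window,
    wheel_radius = wheel_radius, rim_radius = rim_radius,
    system_mass = system_mass,
    shared_variance_frac = shared_variance_frac,
    n_hr_missing = as.integer(min(n_hr_missing, n_participants - 3L)),
    alpha = alpha, normality_alpha = normality_alpha,
    Q = as.integer(Q), n_last_pushes = as.integer(n_last_pushes),
    noise_sd_force = noise_sd_force, noise_sd_torque = noise_sd_torque,
    noise_sd_vo2 = noise_sd_vo2, noise_sd_hr = noise_sd_hr,
    conditions = cond[modalities], rng_seed = as.integer(rng_seed))
  class(cfg) <- "study_config"
  cfg
}

#' Per-modality condition targets (group mean and SD)
#'
#' The generator targets that define the emulated study conditions: push
#' time, cycle time, contact angle, speed, mean push torque, fraction of
#' effective force, negative work per cycle, heart rate, energy
#' expenditure, respiratory exchange ratio and push torque template, per
#' modality. Each numeric entry is `c(mean, sd)`.
#'
#' @return A named list (`OG`, `TM`, `WE`).
#' @export
modality_defaults <- function() {
  list(
    OG = list(push_time = c(0.35, 0.06), cycle_time = c(1.43, 0.47),
              contact_angle = c(71.43, 12.34), speed = c(1.12, 0.02),
              mean_torque = c(4.63, 1.06), fef = c(69.28, 10.33),
              neg_work = c(-1.44, 0.51), hr = c(94.49, 11.80),
              ee = c(208.88, 50.00), rer = 0.91,
              push_shape = "halfsine", shape_rise = 2, shape_fall = 1),
    TM = list(push_time = c(0.35, 0.07), cycle_time = c(1.31, 0.44),
              contact_angle = c(72.28, 13.64), speed = c(1.12, 0.02),
              mean_torque = c(4.34, 1.33), fef = c(69.67, 9.86),
              neg_work = c(-0.50, 0.20), hr = c(89.30, 11.31),
              ee = c(195.97, 40.08), rer = 0.91,
              push_shape = "skewed", shape_rise = 2, shape_fall = 1),
    WE = list(push_time = c(0.32, 0.07), cycle_time = c(1.28, 0.55),
              contact_angle = c(68.74, 14.01), speed = c(1.14, 0.02),
              mean_torque = c(4.65, 1.33), fef = c(73.38, 8.11),
              neg_work = c(-0.42, 0.21), hr = c(92.24, 13.16),
              ee = c(206.31, 42.47), rer = 0.91,
              push_shape = "halfsine", shape_rise = 2, shape_fall = 1))
}

#' Run the end-to-end study replica
#'
#' Simulates the configured cohort (wheel sessions and breath series per
#' participant, modality and block), runs the full analysis chain
#' (last-minute window, zero-phase filtering, push detection, discrete
#' outcomes, physiological outcomes), assembles per-variable outcome
#' tables, computes agreement statistics for every outcome and paired SPM
#' comparisons of the time-normalized torque and total-force profiles for
#' every modality pair. Deterministic given `rng_seed`.
#'
#' @param config a [study_config()].
#' @param verbose print progress to stderr.
#' @return An object of class `propulsion_study`: `config`, `metrics`
#'   (long data frame, one row per participant x modality), `tables`
#'   (named list of participants x modality outcome matrices), `reports`
#'   (named list of [agreement_report()]s), `spm` (nested list
#'   `spm[[variable]][[pair]]`, each with `$rft` and the profile matrices),
#'   `targets` (the per-participant generator targets, the study's ground
#'   truth), `provenance`.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  note <- function(...) if (verbose) message(sprintf(...))
  set.seed(cfg$rng_seed)
  n <- cfg$n_participants
  mods <- cfg$modalities
  vars <- c("push_time", "cycle_time", "contact_angle", "speed",
            "mean_torque", "fef", "neg_work", "hr", "ee")
  # participant effects shared across modalities, per variable
  zp <- matrix(stats::rnorm(n * length(vars)), n,
               dimnames = list(NULL, vars))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             n * length(mods) * (cfg$blocks + 1L)),
                  nrow = n * length(mods))
  hr_missing <- if (cfg$n_hr_missing > 0L) {
    sample.int(n, cfg$n_hr_missing)
  } else {
    integer(0)
  }
  rho <- cfg$shared_variance_frac

  draw <- function(tgt, var, p) {
    mu <- tgt[[var]][1L]; sdv <- tgt[[var]][2L]
    mu + sdv * (sqrt(rho) * zp[p, var] +
                  sqrt(1 - rho) * stats::rnorm(1L))
  }

  metrics <- list()
  targets <- list()
  profiles <- list(torque = list(), total_force = list())
  row_i <- 0L
  for (p in seq_len(n)) {
    for (m in mods) {
      row_i <- row_i + 1L
      tgt <- cfg$conditions[[m]]
      # participant-modality generator targets, kept mutually consistent
      cyc <- max(0.8, draw(tgt, "cycle_time", p))
      pt <- min(max(0.15, draw(tgt, "push_time", p)), cyc - 0.30)
      spd <- max(0.8, draw(tgt, "speed", p))
      ca_max <- 0.95 * spd / cfg$wheel_radius * cyc * 180 / pi
      ca <- min(max(30, draw(tgt, "contact_angle", p)), ca_max)
      mtq <- max(1.5, draw(tgt, "mean_torque", p))
      fef <- min(max(35, draw(tgt, "fef", p)), 97)
      ngw <- min(0, draw(tgt, "neg_work", p))
      hr <- draw(tgt, "hr", p)
      ee <- max(80, draw(tgt, "ee", p))
      vo2 <- ee * 60 / (4940 * tgt$rer + 16040)

      mean_frac <- push_template(list(push_shape = tgt$push_shape,
                                      shape_rise = tgt$shape_rise,
                                      shape_fall = tgt$shape_fall))$mean_frac
      sp <- session_params(
        modality = m, block_duration = cfg$block_duration,
        sample_rate = cfg$sample_rate, wheel_radius = cfg$wheel_radius,
        rim_radius = cfg$rim_radius, system_mass = cfg$system_mass,
        target_speed = spd, push_time = pt, cycle_time = cyc,
        contact_angle = ca, fef_target = fef,
        peak_torque = mtq / mean_frac,
        push_shape = tgt$push_shape, shape_rise = tgt$shape_rise,
        shape_fall = tgt$shape_fall,
        neg_work_per_cycle = ngw,
        noise_sd_force = cfg$noise_sd_force,
        noise_sd_torque = cfg$noise_sd_torque,
        rng_seed = seeds[row_i, 1L])

      bm_list <- list()
      last_sig <- NULL; last_pushes <- NULL
      for (b in seq_len(cfg$blocks)) {
        sp$rng_seed <- seeds[row_i, b]
        ses <- generate_wheel_session(sp)
        win <- last_minute_window(ses$signal, window = cfg$analysis_window)
        filt <- lowpass_filter(win)
        pushes <- detect_pushes(filt)
        bm_list[[b]] <- block_metrics(filt, pushes)
        if (b == cfg$blocks) {
          last_sig <- filt; last_pushes <- pushes
        }
      }
      avg <- function(f) mean(vapply(bm_list, `[[`, numeric(1), f))

      breath <- generate_breath_data(
        vo2_ss = vo2, rer_ss = tgt$rer, hr_ss = hr,
        duration = cfg$block_duration,
        noise_sd_vo2 = cfg$noise_sd_vo2, noise_sd_hr = cfg$noise_sd_hr,
        rng_seed = seeds[row_i, cfg$blocks + 1L])
      if (p %in% hr_missing) breath$hr_bpm <- NA_real_
      ee_hat <- energy_expenditure(breath, window = cfg$analysis_window)
      hr_hat <- mean_heart_rate(breath, window = cfg$analysis_window)
      po_hat <- avg("power_output")

      metrics[[row_i]] <- data.frame(
        participant = p, modality = m,
        n_pushes = avg("n_pushes"),
        push_time = avg("push_time"), cycle_time = avg("cycle_time"),
        contact_angle = avg("contact_angle"), speed = avg("speed"),
        mean_torque = avg("mean_torque"), max_torque = avg("max_torque"),
        work_per_push = avg("work_per_push"), fef = avg("fef"),
        negative_work_per_cycle = avg("negative_work_per_cycle"),
        power_output = po_hat,
        heart_rate = hr_hat, energy_expenditure = ee_hat,
        gross_mechanical_efficiency =
          gross_mechanical_efficiency(po_hat, ee_hat))
      targets[[row_i]] <- data.frame(
        participant = p, modality = m, push_time = pt, cycle_time = cyc,
        contact_angle = ca, speed = spd, mean_torque = mtq, fef = fef,
        negative_work_per_cycle = ngw, heart_rate = hr,
        energy_expenditure = ee)
      for (v in names(profiles)) {
        profiles[[v]][[paste(p, m)]] <-
          normalize_pushes(last_sig, last_pushes, variable = v,
                           Q = cfg$Q, n_last = cfg$n_last_pushes)$values
      }
      note("participant %d / %s done", p, m)
    }
  }
  metrics <- do.call(rbind, metrics)
  targets <- do.call(rbind, targets)

  out_vars <- c("power_output", "speed", "heart_rate",
                "energy_expenditure", "gross_mechanical_efficiency",
                "push_time", "cycle_time", "contact_angle", "fef",
                "mean_torque", "max_torque", "work_per_push",
                "negative_work_per_cycle")
  tables <- lapply(out_vars, function(v) {
    tab <- sapply(mods, function(m) {
      metrics[[v]][metrics$modality == m][order(
        metrics$participant[metrics$modality == m])]
    })
    rownames(tab) <- seq_len(n)
    tab
  })
  names(tables) <- out_vars

  reports <- lapply(out_vars, function(v) {
    agreement_report(tables[[v]], variable = v, alpha = cfg$alpha,
                     normality_alpha = cfg$normality_alpha)
  })
  names(reports) <- out_vars

  pairs <- utils::combn(mods, 2L)
  spm <- lapply(c("torque", "total_force"), function(v) {
    pr <- lapply(seq_len(ncol(pairs)), function(j) {
      m1 <- pairs[1L, j]; m2 <- pairs[2L, j]
      ya <- do.call(rbind, profiles[[v]][paste(seq_len(n), m1)])
      yb <- do.call(rbind, profiles[[v]][paste(seq_len(n), m2)])
      list(pair = paste(m1, "vs", m2), a = ya, b = yb,
           rft = spm_paired_t(ya, yb, alpha = cfg$alpha))
    })
    names(pr) <- apply(pairs, 2L, paste, collapse = " vs ")
    pr
  })
  names(spm) <- c("torque", "total_force")

  structure(list(
    config = cfg, metrics = metrics, tables = tables, reports = reports,
    spm = spm, targets = targets,
    provenance = list(rng_seed = cfg$rng_seed,
                      package_version = as.character(
                        utils::packageVersion("propulsim")),
                      r_version = R.version.string,
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "propulsion_study")
}

#' @export
print.propulsion_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Propulsion study replica: %d participants x %s, %d block(s)\n",
              cfg$n_participants, paste(cfg$modalities, collapse = "/"),
              cfg$blocks))
  cat(sprintf("  seed %d; %d outcome variables; SPM on torque and total force\n",
              cfg$rng_seed, length(x$reports)))
  sig <- vapply(x$spm, function(v) {
    sum(vapply(v, function(p) nrow(p$rft$clusters) > 0, logical(1)))
  }, numeric(1))
  cat(sprintf("  SPM comparisons with supra-threshold clusters: torque %d, total force %d\n",
              sig["torque"], sig["total_force"]))
  invisible(x)
}

#' @export
summary.propulsion_study <- function(object, ...) {
  for (r in object$reports) print(r)
  invisible(object)
}

#' Write the study report bundle
#'
#' Writes per-participant metrics (CSV), the outcome-table report in the
#' layout of the study's summary table (CSV: per-condition mean/SD, ICC
#' with CI and label per pair, omnibus and pairwise p-values with effect
#' sizes), the SPM cluster table (JSON) and a provenance record (JSON).
#'
#' @param study a `propulsion_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "propulsion_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  rows <- lapply(study$reports, function(r) {
    icc_txt <- vapply(r$icc, function(ic) {
      if (is.null(ic$icc) || is.na(ic$icc$icc)) {
        sprintf("%s: undefined", ic$pair)
      } else {
        sprintf("%s: %.2f (%.2f-%.2f) [%s]", ic$pair, ic$icc$icc,
                ic$icc$ci95[1L], ic$icc$ci95[2L], ic$icc$label)
      }
    }, character(1))
    pw_txt <- if (is.null(r$pairwise)) {
      "n.s. omnibus"
    } else {
      paste(sprintf("%s: p=%.3f, %s=%.2f [%s]", r$pairwise$pair,
                    r$pairwise$p, r$pairwise$effect_type,
                    r$pairwise$effect_size, r$pairwise$effect_band),
            collapse = "; ")
    }
    data.frame(
      variable = r$variable,
      t(stats::setNames(sprintf("%.3f (%.3f)", r$summary$mean,
                                r$summary$sd), r$summary$condition)),
      icc = paste(icc_txt, collapse = "; "),
      omnibus_test = if (is.null(r$omnibus)) NA else r$omnibus$test_name,
      omnibus_p = if (is.null(r$omnibus)) NA else r$omnibus$p,
      pairwise = pw_txt)
  })
  utils::write.csv(do.call(rbind, rows),
                   file.path(dir, "table1_report.csv"), row.names = FALSE)
  clusters <- lapply(study$spm, function(v) {
    lapply(v, function(pr) {
      list(pair = pr$pair, t_critical = pr$rft$t_critical,
           fwhm_pct = pr$rft$fwhm_pct, clusters = pr$rft$clusters)
    })
  })
  jsonlite::write_json(clusters, file.path(dir, "spm_clusters.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(study$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
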