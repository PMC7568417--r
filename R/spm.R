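#' Time-normalize push profiles
#'
#' Resamples each of the last `n_last` pushes to `Q` nodes spanning
#' 0-100% of its own push phase by cubic interpolation, then averages
#' within the participant-condition, yielding one mean profile per
#' participant and condition as input for continuous (SPM) analysis.
#'
#' @param signal a `wheel_signal` the pushes belong to.
#' @param pushes a [push_table][detect_pushes()].
#' @param variable profile variable: axle torque (`"torque"`, Nm) or total
#'   force magnitude (`"total_force"`, N).
#' @param Q number of nodes on the normalized 0-100% domain.
#' @param n_last number of final pushes to use; if fewer are available all
#'   are used with a warning.
#' @return An object of class `normalized_profile`: `values` (length `Q`
#'   mean profile), `per_push` (pushes x Q matrix), `variable`, `Q`,
#'   `n_used`. Pushes shorter than 4 samples are skipped with a warning
#'   (cubic interpolation infeasible).
#' @export
normalize_pushes <- function(signal, pushes,
                             variable = c("torque", "total_force"),
                             Q = 101, n_last = 20) {
  stopifnot(inherits(signal, "wheel_signal"), inherits(pushes, "push_table"))
  variable <- match.arg(variable)
  k <- nrow(pushes)
  if (k == 0L) stop("no pushes to normalize", call. = FALSE)
  if (k < n_last) {
    warning(sprintf("only %d pushes available (%d requested); using all",
                    k, n_last))
  }
  use <- pushes[max(1L, k - n_last + 1L):k, , drop = FALSE]
  chan <- if (variable == "torque") {
    signal$torque
  } else {
    sqrt(signal$fx^2 + signal$fy^2 + signal$fz^2)
  }
  nodes <- seq(0, 1, length.out = Q)
  prof <- lapply(seq_len(nrow(use)), function(i) {
    span <- use$start[i]:(use$end[i] - 1L)     # half-open push interval
    if (length(span) < 4L) {
      warning("push shorter than 4 samples skipped")
      return(NULL)
    }
    v <- chan[span]
    xi <- seq(0, 1, length.out = length(v))
    stats::splinefun(xi, v, method = "fmm")(nodes)
  })
  prof <- prof[!vapply(prof, is.null, logical(1))]
  if (!length(prof)) stop("no usable pushes after skipping", call. = FALSE)
  m <- do.call(rbind, prof)
  structure(list(values = colMeans(m), per_push = m, variable = variable,
                 Q = Q, n_used = nrow(m)),
            class = "normalized_profile")
}

#' Paired 1-D SPM t-test with random-field-theory inference
#'
#' Computes a pointwise paired t-statistic field over the normalized push
#' phase and performs family-wise inference with 1-D random field theory
#' (RFT): the smoothness (FWHM) of the residual difference fields is
#' estimated from their normalized gradients, the search volume in resels
#' is `(Q-1)/FWHM`, and the critical threshold solves the expected-Euler-
#' characteristic equation for a 1-D t-field
#' \deqn{\alpha = P(T > u) + R \frac{\sqrt{4\log 2}}{2\pi}
#'   (1 + u^2/\nu)^{-(\nu-1)/2}}
#' (doubled for two-sided inference on |t|). Supra-threshold clusters get
#' p-values from the standard 1-D Poisson-clumping approximation with an
#' exponential cluster-extent distribution calibrated to the expected
#' suprathreshold volume per cluster.
#'
#' In the maximal-smoothness limit (flat residuals, resels -> 0) the
#' threshold reduces to the scalar two-sided critical value
#' `qt(1 - alpha/2, n - 1)`.
#'
#' @param profiles_a,profiles_b matrices (participants x Q) of matched mean
#'   profiles, or lists of `normalized_profile` objects in matching
#'   participant order.
#' @param alpha family-wise significance level.
#' @param two_sided if `TRUE` (default) inference is on `|t|`.
#' @return An object of class `spm_t`: `t` (length-Q field, `NA` at
#'   zero-variance nodes), `df`, `fwhm_nodes`, `fwhm_pct`, `resels`,
#'   `t_critical`, `clusters` (data frame `start_pct`, `end_pct`,
#'   `extent_pct`, `max_t`, `p`), `alpha`, `two_sided`, `n`, `Q`,
#'   `mean_a`, `mean_b`, `sd_a`, `sd_b`.
#' @export
spm_paired_t <- function(profiles_a, profiles_b, alpha = 0.05,
                         two_sided = TRUE) {
  ya <- profile_matrix(profiles_a)
  yb <- profile_matrix(profiles_b)
  if (!all(dim(ya) == dim(yb))) {
    stop("profile sets must be matched participants x nodes matrices",
         call. = FALSE)
  }
  n <- nrow(ya); Q <- ncol(ya)
  if (n < 3L) stop("paired SPM needs at least 3 participants", call. = FALSE)
  d <- ya - yb
  m <- colMeans(d)
  s <- apply(d, 2L, stats::sd)
  tfield <- m / (s / sqrt(n))
  zv <- s < 1e-12
  if (any(zv)) {
    if (!all(zv)) {
      warning(sprintf("%d zero-variance node(s) masked in the t-field",
                      sum(zv)))
    }
    tfield[zv] <- NA_real_
  }
  df <- n - 1
  resid <- d - matrix(m, n, Q, byrow = TRUE)
  fwhm <- estimate_fwhm(resid)
  resels <- (Q - 1) / fwhm
  tcrit <- rft_threshold(alpha, df, resels, two_sided = two_sided)
  clusters <- field_clusters(tfield, tcrit, two_sided = two_sided)
  if (nrow(clusters)) {
    clusters$p <- vapply(seq_len(nrow(clusters)), function(i) {
      rft_cluster_p(clusters$extent_nodes[i] / fwhm, tcrit, df, resels,
                    two_sided = two_sided)
    }, numeric(1))
    clusters$start_pct <- clusters$start_node / (Q - 1) * 100
    clusters$end_pct <- clusters$end_node / (Q - 1) * 100
    clusters$extent_pct <- clusters$extent_nodes / (Q - 1) * 100
  } else {
    clusters$p <- numeric(0)
    clusters$start_pct <- numeric(0)
    clusters$end_pct <- numeric(0)
    clusters$extent_pct <- numeric(0)
  }
  structure(list(
    t = tfield, df = df, fwhm_nodes = fwhm,
    fwhm_pct = fwhm / (Q - 1) * 100, resels = resels, t_critical = tcrit,
    clusters = clusters[, c("start_pct", "end_pct", "extent_pct",
                            "max_t", "p")],
    alpha = alpha, two_sided = two_sided, n = n, Q = Q,
    mean_a = colMeans(ya), mean_b = colMeans(yb),
    sd_a = apply(ya, 2L, stats::sd), sd_b = apply(yb, 2L, stats::sd)
  ), class = "spm_t")
}

profile_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "normalized_profile")) return(matrix(x$values, nrow = 1L))
  if (is.list(x)) {
    return(do.call(rbind, lapply(x, function(p) {
      if (inherits(p, "normalized_profile")) p$values else as.numeric(p)
    })))
  }
  stop("cannot interpret profiles; give a matrix or list of normalized_profile",
       call. = FALSE)
}

# Residual-gradient FWHM estimator for a 1-D random field (node units).
# For residual rows r_i(q): lambda(q) = sum_i r_i'(q)^2 / sum_i r_i(q)^2,
# resels per node = sqrt(lambda / (4 log 2)), FWHM = 1 / mean(resels/node).
estimate_fwhm <- function(resid) {
  ssq <- colSums(resid^2)
  g <- row_gradient(resid)
  v <- colSums(g^2) / (ssq + .Machine$double.eps)
  v <- v[is.finite(v) & ssq > 1e-24]
  if (!length(v)) return(Inf)
  rpn <- sqrt(v / (4 * log(2)))
  if (mean(rpn) < .Machine$double.eps) return(Inf)
  1 / mean(rpn)
}

# per-row numerical gradient (central differences, one-sided at the ends)
row_gradient <- function(m) {
  Q <- ncol(m)
  g <- matrix(0, nrow(m), Q)
  if (Q >= 3L) g[, 2:(Q - 1L)] <- (m[, 3:Q] - m[, 1:(Q - 2L)]) / 2
  g[, 1L] <- m[, 2L] - m[, 1L]
  g[, Q] <- m[, Q] - m[, Q - 1L]
  g
}

# expected Euler characteristic of a 1-D t-field above u over R resels
rft_expected_ec <- function(u, df, resels) {
  stats::pt(u, df, lower.tail = FALSE) +
    resels * sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
}

#' RFT critical threshold for a 1-D t-field
#'
#' Solves the expected-Euler-characteristic equation for the threshold `u`
#' at which the family-wise excursion probability of a smooth 1-D t-field
#' equals `alpha`.
#'
#' @param alpha family-wise level.
#' @param df degrees of freedom of the t-field.
#' @param resels search volume in resolution elements, `(Q-1)/FWHM`.
#' @param two_sided inference on `|t|`.
#' @return The critical value.
#' @export
rft_threshold <- function(alpha, df, resels, two_sided = TRUE) {
  a <- if (two_sided) alpha / 2 else alpha
  f <- function(u) rft_expected_ec(u, df, resels) - a
  upper <- 100
  if (f(upper) > 0) stop("RFT threshold solve failed", call. = FALSE)
  stats::uniroot(f, c(1e-3, upper), tol = 1e-10)$root
}

# cluster-extent p-value (Poisson clumping, exponential extents);
# extent k in resel units at threshold u
rft_cluster_p <- function(k_resels, u, df, resels, two_sided = TRUE) {
  side <- if (two_sided) 2 else 1
  e_m <- side * resels * sqrt(4 * log(2)) / (2 * pi) *
    (1 + u^2 / df)^(-(df - 1) / 2)
  e_nvol <- side * resels * stats::pt(u, df, lower.tail = FALSE)
  if (e_m <= 0) return(NA_real_)
  e_extent <- e_nvol / e_m
  p <- 1 - exp(-e_m * exp(-k_resels / max(e_extent, 1e-12)))
  min(max(p, .Machine$double.eps), 1)
}

# maximal supra-threshold runs of |t| (or t), endpoints interpolated to the
# threshold crossing; node coordinates are 0-based (0 .. Q-1)
field_clusters <- function(tfield, u, two_sided = TRUE) {
  z <- if (two_sided) abs(tfield) else tfield
  z[!is.finite(z)] <- -Inf
  above <- z > u
  Q <- length(z)
  out <- data.frame(start_node = numeric(0), end_node = numeric(0),
                    extent_nodes = numeric(0), max_t = numeric(0))
  if (!any(above)) return(out)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    s_node <- if (s > 1L && is.finite(z[s - 1L])) {
      (s - 2) + (u - z[s - 1L]) / (z[s] - z[s - 1L])
    } else {
      s - 1
    }
    e_node <- if (e < Q && is.finite(z[e + 1L])) {
      (e - 1) + (z[e] - u) / (z[e] - z[e + 1L])
    } else {
      e - 1
    }
    seg <- tfield[s:e]
    out <- rbind(out, data.frame(
      start_node = s_node, end_node = e_node,
      extent_nodes = e_node - s_node,
      max_t = seg[which.max(abs(seg))]))    # signed extreme value
  }
  out
}

#' @export
print.spm_t <- function(x, ...) {
  cat(sprintf("Paired SPM t-field: n = %d, df = %d, Q = %d nodes\n",
              x$n, x$df, x$Q))
  cat(sprintf("  FWHM = %.1f nodes (%.1f%% of domain), resels = %.2f\n",
              x$fwhm_nodes, x$fwhm_pct, x$resels))
  cat(sprintf("  %s RFT threshold at alpha = %g: t* = %.3f\n",
              if (x$two_sided) "two-sided" else "one-sided",
              x$alpha, x$t_critical))
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %d: %.1f-%.1f%% of push phase, max t = %.2f, p = %.4f\n",
                  i, x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$max_t[i], x$clusters$p[i]))
    }
  } else {
    cat("  no supra-threshold clusters\n")
  }
  invisible(x)
}

#' Plot a paired SPM comparison
#'
#' Two panels: mean +/- SD profiles of both conditions over the normalized
#' push phase, and the paired t-field with the RFT threshold and any
#' supra-threshold clusters shaded.
#'
#' @param x an `spm_t` object.
#' @param labels length-2 condition labels.
#' @param ... passed to the profile panel's `plot()`.
#' @export
plot.spm_t <- function(x, labels = c("A", "B"), ...) {
  pct <- seq(0, 100, length.out = x$Q)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  ylim <- range(x$mean_a + x$sd_a, x$mean_a - x$sd_a,
                x$mean_b + x$sd_b, x$mean_b - x$sd_b)
  graphics::plot(pct, x$mean_a, type = "l", col = "black", ylim = ylim,
                 xlab = "push phase (%)", ylab = "profile", ...)
  graphics::polygon(c(pct, rev(pct)),
                    c(x$mean_a + x$sd_a, rev(x$mean_a - x$sd_a)),
                    col = grDevices::adjustcolor("black", 0.15), border = NA)
  graphics::lines(pct, x$mean_b, col = "red")
  graphics::polygon(c(pct, rev(pct)),
                    c(x$mean_b + x$sd_b, rev(x$mean_b - x$sd_b)),
                    col = grDevices::adjustcolor("red", 0.15), border = NA)
  graphics::legend("topright", legend = labels, col = c("black", "red"),
                   lty = 1, bty = "n")
  graphics::plot(pct, x$t, type = "l", xlab = "push phase (%)",
                 ylab = "SPM {t}")
  graphics::abline(h = c(-1, 1) * x$t_critical, lty = 2, col = "red")
  graphics::abline(h = 0, col = "grey")
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters))) {
      graphics::rect(x$clusters$start_pct[i], graphics::par("usr")[3L],
                     x$clusters$end_pct[i], graphics::par("usr")[4L],
                     col = grDevices::adjustcolor("red", 0.1), border = NA)
    }
  }
  invisible(x)
}

#' Sign-flip permutation inference for a paired 1-D t-field
#'
#' Nonparametric counterpart of [spm_paired_t()]: the null distribution of
#' the field maximum of |t| is built by flipping the signs of the
#' participant difference fields. The critical threshold is the
#' `1 - alpha` quantile of the permutation max-|t| distribution; cluster
#' p-values come from the permutation null of the maximal supra-threshold
#' cluster mass (integral of `|t| - u` over a cluster).
#'
#' All `2^n` sign patterns are enumerated when that is no more than
#' `n_perm`; otherwise `n_perm` random patterns (including the identity)
#' are sampled.
#'
#' @param profiles_a,profiles_b matched profile matrices as in
#'   [spm_paired_t()].
#' @param alpha family-wise level.
#' @param n_perm maximum number of permutations.
#' @param rng_seed integer seed for sampled permutations.
#' @param two_sided inference on `|t|`.
#' @return An object of class `spm_perm`: `t`, `t_critical`, `clusters`
#'   (with permutation `p`), `n_perm_used`, `exhaustive`, `max_dist`
#'   (permutation distribution of the field maximum), `alpha`, `n`, `Q`.
#' @export
spm_permutation <- function(profiles_a, profiles_b, alpha = 0.05,
                            n_perm = 1000, rng_seed = 1L, two_sided = TRUE) {
  if (n_perm < 100) warning("fewer than 100 permutations is unreliable")
  ya <- profile_matrix(profiles_a)
  yb <- profile_matrix(profiles_b)
  stopifnot(all(dim(ya) == dim(yb)))
  d <- ya - yb
  n <- nrow(d); Q <- ncol(d)
  if (n < 3L) stop("paired SPM needs at least 3 participants", call. = FALSE)

  exhaustive <- 2^n <= n_perm
  signs <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    set.seed(rng_seed)
    s <- matrix(sample(c(-1, 1), (n_perm - 1L) * n, replace = TRUE),
                ncol = n)
    rbind(rep(1, n), s)
  }
  P <- nrow(signs)
  ssq <- colSums(d^2)                  # invariant under sign flips
  M <- (signs %*% d) / n               # P x Q permutation means
  V <- sweep(-n * M^2, 2L, ssq, "+") / (n - 1)
  V[V < 0] <- 0
  Tm <- M / sqrt(V / n)
  Tm[!is.finite(Tm)] <- NA_real_
  Za <- if (two_sided) abs(Tm) else Tm
  max_dist <- apply(Za, 1L, function(r) {
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  })
  if (all(is.na(max_dist))) {
    # degenerate: identical inputs, no variability anywhere
    obs_t <- rep(NA_real_, Q)
    out <- list(t = obs_t, t_critical = NA_real_,
                clusters = data.frame(start_pct = numeric(0),
                                      end_pct = numeric(0),
                                      extent_pct = numeric(0),
                                      max_t = numeric(0), p = numeric(0)),
                n_perm_used = P, exhaustive = exhaustive,
                max_dist = max_dist, alpha = alpha, n = n, Q = Q)
    class(out) <- "spm_perm"
    return(out)
  }
  u <- stats::quantile(max_dist, 1 - alpha, na.rm = TRUE, names = FALSE)

  m0 <- colMeans(d)
  s0 <- apply(d, 2L, stats::sd)
  obs_t <- m0 / (s0 / sqrt(n))
  obs_t[s0 < 1e-12] <- NA_real_

  cl <- field_clusters(obs_t, u, two_sided = two_sided)
  if (nrow(cl)) {
    # permutation null of the maximal cluster mass at threshold u
    mass_of <- function(row) {
      z <- row; z[!is.finite(z)] <- -Inf
      excess <- pmax(z - u, 0)
      if (!any(excess > 0)) return(0)
      r <- rle(excess > 0)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      max(vapply(which(r$values), function(i) {
        sum(excess[starts[i]:ends[i]])
      }, numeric(1)))
    }
    null_mass <- apply(Za, 1L, mass_of)
    cl$p <- vapply(seq_len(nrow(cl)), function(i) {
      s <- which.min(abs(seq(0, Q - 1) - cl$start_node[i]))
      e <- which.min(abs(seq(0, Q - 1) - cl$end_node[i]))
      z <- if (two_sided) abs(obs_t[s:e]) else obs_t[s:e]
      obs_mass <- sum(pmax(z - u, 0), na.rm = TRUE)
      (1 + sum(null_mass >= obs_mass, na.rm = TRUE)) / (1 + P)
    }, numeric(1))
    cl$start_pct <- cl$start_node / (Q - 1) * 100
    cl$end_pct <- cl$end_node / (Q - 1) * 100
    cl$extent_pct <- cl$extent_nodes / (Q - 1) * 100
  } else {
    cl$p <- numeric(0)
    cl$start_pct <- numeric(0); cl$end_pct <- numeric(0)
    cl$extent_pct <- numeric(0)
  }
  out <- list(t = obs_t, t_critical = u,
              clusters = cl[, c("start_pct", "end_pct", "extent_pct",
                                "max_t", "p")],
              n_perm_used = P, exhaustive = exhaustive,
              max_dist = max_dist, alpha = alpha, n = n, Q = Q)
  class(out) <- "spm_perm"
  out
}

#' @export
print.spm_perm <- function(x, ...) {
  cat(sprintf("Permutation SPM: n = %d, Q = %d, %d permutations%s\n",
              x$n, x$Q, x$n_perm_used,
              if (x$exhaustive) " (exhaustive)" else ""))
  cat(sprintf("  max-|t| threshold at alpha = %g: %.3f\n",
              x$alpha, x$t_critical))
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %d: %.1f-%.1f%%, max t = %.2f, p = %.4f\n",
                  i, x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$max_t[i], x$clusters$p[i]))
    }
  } else {
    cat("  no supra-threshold clusters\n")
  }
  invisible(x)
}

#' Smooth Gaussian 1-D null fields
#'
#' Generates `n` independent smooth Gaussian fields of length `Q` by
#' convolving white noise with a Gaussian kernel of the given FWHM, the
#' standard null model for validating 1-D random-field inference. The
#' kernel columns are scaled so every node has unit marginal variance.
#'
#' @param n number of fields (rows).
#' @param Q number of nodes.
#' @param fwhm kernel full width at half maximum, in nodes.
#' @param rng_seed integer seed (`NULL` leaves the RNG state alone).
#' @return An `n` x `Q` matrix.
#' @export
smooth_gaussian_fields <- function(n, Q, fwhm = 20, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  idx <- seq_len(Q)
  kern <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  kern <- sweep(kern, 2L, sqrt(colSums(kern^2)), "/")   # unit variance
  w <- matrix(stats::rnorm(n * Q), n, Q)
  w %*% kern
}
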