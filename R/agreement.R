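#' Intraclass correlation ICC(2,1): two-way random effects, absolute
#' agreement, single rater
#'
#' Computes the absolute-agreement single-measure ICC from the two-way
#' mean-squares decomposition
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' with rows = subjects (n) and columns = conditions/raters (k), together
#' with the F-based 95% confidence interval of McGraw & Wong (using a
#' Satterthwaite degrees-of-freedom approximation) and the significance test
#' `F = MSR/MSE` on `(n-1, (n-1)(k-1))` degrees of freedom.
#'
#' The qualitative label follows the conventional bands: below 0.50 poor,
#' 0.50-0.75 moderate, 0.75-0.90 good, above 0.90 excellent; a
#' non-significant ICC (p >= `alpha`) is labeled `"n.s."`. With no
#' between-subject variance the ICC is undefined and reported as such
#' (label `"undefined"`), which happens for outcomes with coefficients of
#' variation near zero.
#'
#' @param ratings numeric matrix or data frame, subjects in rows and
#'   conditions in columns; rows with missing values are dropped
#'   (complete-case).
#' @param alpha significance/confidence level (two-sided CI at `1 - alpha`).
#' @return An object of class `icc_agreement`: `icc`, `ci95 = c(low, high)`,
#'   `p`, `label`, `n`, `k`, and the mean squares `MSR`, `MSC`, `MSE`.
#' @export
icc_2_1 <- function(ratings, alpha = 0.05) {
  x <- as.matrix(ratings)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 3L || k < 2L) {
    stop("ICC(2,1) needs at least 3 complete subjects and 2 conditions",
         call. = FALSE)
  }
  grand <- mean(x)
  rm <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sse <- sum((x - outer(rm, rep(1, k)) - outer(rep(1, n), cm) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (!is.finite(denom) || abs(denom) < 1e-12) {
    out <- list(icc = NA_real_, ci95 = c(NA_real_, NA_real_), p = NA_real_,
                label = "undefined", n = n, k = k,
                MSR = msr, MSC = msc, MSE = mse)
    class(out) <- "icc_agreement"
    return(out)
  }
  icc <- (msr - mse) / denom

  # significance of ICC > 0
  f0 <- msr / mse
  p <- stats::pf(f0, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)

  # McGraw & Wong F-based CI for ICC(A,1)
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)

  label <- if (!is.finite(p) || p >= alpha) {
    "n.s."
  } else if (icc < 0.50) {
    "poor"
  } else if (icc < 0.75) {
    "moderate"
  } else if (icc <= 0.90) {
    "good"
  } else {
    "excellent"
  }
  out <- list(icc = icc, ci95 = c(lo, hi), p = p, label = label,
              n = n, k = k, MSR = msr, MSC = msc, MSE = mse)
  class(out) <- "icc_agreement"
  out
}

#' @export
print.icc_agreement <- function(x, ...) {
  if (is.na(x$icc)) {
    cat("ICC(2,1): undefined (no between-subject variance)\n")
  } else {
    cat(sprintf("ICC(2,1) = %.3f (95%% CI %.3f-%.3f), p = %.4f [%s]\n",
                x$icc, x$ci95[1L], x$ci95[2L], x$p, x$label))
    cat(sprintf("  n = %d subjects, k = %d conditions\n", x$n, x$k))
  }
  invisible(x)
}

#' Omnibus test across conditions with a normality screen
#'
#' Runs a one-way repeated-measures ANOVA across the conditions of a
#' subjects-by-conditions table, unless a Shapiro-Wilk screen (at
#' `normality_alpha`, applied per condition) rejects normality for any
#' condition, in which case a Friedman test is used instead. Constant
#' columns are treated as non-normal. Rows with missing values are dropped.
#'
#' @param table numeric matrix/data frame, subjects x conditions (>= 3
#'   conditions for a meaningful omnibus; k = 2 is allowed and equivalent
#'   to a paired comparison).
#' @param normality_alpha level of the Shapiro-Wilk screen.
#' @param force `NULL` for automatic selection, or `"anova"` / `"friedman"`.
#' @return A list: `test_name` (`"RM-ANOVA"` or `"Friedman"`), `statistic`
#'   (F or chi-squared), `df` (length-2 or length-1), `p`, `normal`
#'   (screen outcome).
#' @export
omnibus_test <- function(table, normality_alpha = 0.05, force = NULL) {
  x <- as.matrix(table)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) stop("omnibus test needs at least 3 subjects", call. = FALSE)
  if (k < 2L) stop("omnibus test needs at least 2 conditions", call. = FALSE)

  normal <- all(apply(x, 2L, function(col) {
    if (stats::sd(col) < 1e-12) return(FALSE)
    tryCatch(stats::shapiro.test(col)$p.value >= normality_alpha,
             error = function(e) FALSE)
  }))
  use_anova <- if (is.null(force)) normal else identical(force, "anova")

  if (use_anova) {
    subj <- factor(rep(seq_len(n), k))
    cond <- factor(rep(seq_len(k), each = n))
    y <- as.vector(x)
    ss_cond <- n * sum((colMeans(x) - mean(x))^2)
    if (ss_cond < 1e-12 * max(1, sum((y - mean(y))^2))) {
      # no condition effect at all: F = 0 by convention (avoids 0/0 when
      # the residual variance also vanishes, e.g. identical columns)
      return(list(test_name = "RM-ANOVA", statistic = 0,
                  df = c(k - 1, (n - 1) * (k - 1)), p = 1, normal = normal))
    }
    fit <- stats::aov(y ~ cond + Error(subj))
    tab <- summary(fit)[["Error: Within"]][[1L]]
    list(test_name = "RM-ANOVA",
         statistic = tab["cond", "F value"],
         df = c(tab["cond", "Df"], tab["Residuals", "Df"]),
         p = tab["cond", "Pr(>F)"],
         normal = normal)
  } else {
    ft <- stats::friedman.test(x)
    list(test_name = "Friedman",
         statistic = unname(ft$statistic),
         df = unname(ft$parameter),
         p = ft$p.value,
         normal = normal)
  }
}

#' Planned pairwise comparisons with effect sizes
#'
#' Uncorrected paired comparisons between all condition pairs: paired
#' t-tests with the paired Cohen's d (`mean(diff)/sd(diff)`), or exact
#' Wilcoxon signed-rank tests with the matched-pairs rank-biserial
#' correlation `r = (W+ - W-)/(W+ + W-)`. No multiplicity adjustment is
#' applied (a deliberate maximize-sensitivity choice). Effect-size bands:
#' |es| < 0.2 small, 0.2-0.5 medium, > 0.5 large.
#'
#' @param table numeric matrix/data frame, subjects x conditions (with
#'   column names used as condition labels).
#' @param parametric logical: paired t-tests (`TRUE`) or Wilcoxon
#'   signed-rank tests (`FALSE`).
#' @return A data frame with one row per pair: `pair`, `test`, `statistic`,
#'   `p`, `effect_size`, `effect_type` (`"cohens_d"` or `"rank_biserial"`),
#'   `effect_band`.
#' @export
pairwise_tests <- function(table, parametric = TRUE) {
  x <- as.matrix(table)
  k <- ncol(x)
  if (k < 2L) stop("need at least 2 conditions", call. = FALSE)
  labs <- colnames(x)
  if (is.null(labs)) labs <- paste0("C", seq_len(k))
  pairs <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    ok <- stats::complete.cases(x[, c(i1, i2)])
    a <- x[ok, i1]; b <- x[ok, i2]
    d <- a - b
    if (parametric) {
      sdd <- stats::sd(d)
      if (sdd < 1e-12) {
        es <- NA_real_
        tt <- list(statistic = NA_real_, p.value = NA_real_)
        warning("zero-variance differences; Cohen's d undefined for pair ",
                labs[i1], "-", labs[i2])
      } else {
        tt <- stats::t.test(a, b, paired = TRUE)
        es <- mean(d) / sdd
      }
      data.frame(pair = paste(labs[i1], "vs", labs[i2]), test = "paired t",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 effect_size = es, effect_type = "cohens_d",
                 effect_band = effect_band(es))
    } else {
      dd <- d[d != 0]
      nn <- length(dd)
      wt <- suppressWarnings(
        stats::wilcox.test(a, b, paired = TRUE, exact = nn <= 25))
      wpos <- sum(rank(abs(dd))[dd > 0])
      wtot <- nn * (nn + 1) / 2
      es <- if (wtot > 0) (2 * wpos - wtot) / wtot else NA_real_
      data.frame(pair = paste(labs[i1], "vs", labs[i2]),
                 test = "wilcoxon signed-rank",
                 statistic = unname(wt$statistic), p = wt$p.value,
                 effect_size = es, effect_type = "rank_biserial",
                 effect_band = effect_band(es))
    }
  })
  do.call(rbind, rows)
}

effect_band <- function(es) {
  if (is.na(es)) return(NA_character_)
  a <- abs(es)
  if (a < 0.2) "small" else if (a <= 0.5) "medium" else "large"
}

#' Cross-modality agreement report for one outcome variable
#'
#' Assembles, for one subjects-by-conditions outcome table, the per-condition
#' mean and SD, the pairwise ICC(2,1) with CI and label, the omnibus test
#' (RM-ANOVA or Friedman per normality screen), and — when the omnibus is
#' significant at `alpha` — the planned pairwise comparisons with effect
#' sizes (parametric when the screen passed).
#'
#' @param table numeric matrix/data frame, subjects x conditions.
#' @param variable variable name used in the report.
#' @param alpha significance level.
#' @param normality_alpha level of the Shapiro-Wilk screen.
#' @param pairwise_always run pairwise comparisons even without a
#'   significant omnibus.
#' @return An object of class `agreement_report`: `variable`, `summary`
#'   (per-condition mean/sd/n), `icc` (list per pair), `omnibus`,
#'   `pairwise` (data frame or `NULL`).
#' @export
agreement_report <- function(table, variable = "outcome", alpha = 0.05,
                             normality_alpha = 0.05,
                             pairwise_always = FALSE) {
  x <- as.matrix(table)
  labs <- colnames(x)
  if (is.null(labs)) labs <- paste0("C", seq_len(ncol(x)))
  summ <- data.frame(
    condition = labs,
    mean = apply(x, 2L, mean, na.rm = TRUE),
    sd = apply(x, 2L, stats::sd, na.rm = TRUE),
    n = apply(x, 2L, function(v) sum(!is.na(v))),
    row.names = NULL)
  pairs <- utils::combn(ncol(x), 2L)
  iccs <- lapply(seq_len(ncol(pairs)), function(j) {
    sub <- x[, pairs[, j], drop = FALSE]
    res <- tryCatch(icc_2_1(sub, alpha = alpha),
                    error = function(e) NULL)
    list(pair = paste(labs[pairs[1L, j]], "vs", labs[pairs[2L, j]]),
         icc = res)
  })
  omni <- if (ncol(x) >= 3L) {
    omnibus_test(x, normality_alpha = normality_alpha)
  } else {
    NULL
  }
  run_pairwise <- pairwise_always || is.null(omni) ||
    (is.finite(omni$p) && omni$p < alpha)
  pw <- if (run_pairwise) {
    parametric <- is.null(omni) || omni$normal
    pairwise_tests(x, parametric = parametric)
  } else {
    NULL
  }
  structure(list(variable = variable, summary = summ, icc = iccs,
                 omnibus = omni, pairwise = pw),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report:", x$variable, "\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-4s %8.3f (%.3f)  n = %d\n", x$summary$condition[i],
                x$summary$mean[i], x$summary$sd[i], x$summary$n[i]))
  }
  for (ic in x$icc) {
    if (is.null(ic$icc)) next
    v <- ic$icc
    if (is.na(v$icc)) {
      cat(sprintf("  ICC %s: undefined\n", ic$pair))
    } else {
      cat(sprintf("  ICC %s: %.2f (%.2f-%.2f) [%s]\n", ic$pair, v$icc,
                  v$ci95[1L], v$ci95[2L], v$label))
    }
  }
  if (!is.null(x$omnibus)) {
    cat(sprintf("  omnibus %s: stat = %.3f, p = %.4f\n",
                x$omnibus$test_name, x$omnibus$statistic, x$omnibus$p))
  }
  if (!is.null(x$pairwise)) {
    for (i in seq_len(nrow(x$pairwise))) {
      cat(sprintf("  %s (%s): p = %.4f, %s = %.2f [%s]\n",
                  x$pairwise$pair[i], x$pairwise$test[i], x$pairwise$p[i],
                  x$pairwise$effect_type[i], x$pairwise$effect_size[i],
                  x$pairwise$effect_band[i]))
    }
  }
  invisible(x)
}
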