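#' Pearson correlation
#'
#' Sample product-moment correlation between two vectors; errors on
#' constant input, where the correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return Correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_config("x and y lengths differ")
  if (length(x) < 3L) stop_config("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_config("correlation undefined for constant input")
  stats::cor(x, y)
}

#' Paired t-test
#'
#' Computed from the difference formula \code{t = mean(d) / (sd(d) /
#' sqrt(n))} with \code{d = x - y} and a two-sided p-value from the
#' Student t distribution on \code{n - 1} degrees of freedom.  When all
#' differences are identical and nonzero the statistic is infinite and
#' p = 0; when x equals y exactly, t = 0 and p = 1.
#'
#' @param x,y Paired numeric vectors, n >= 2.
#' @return List with \code{t}, \code{df} and \code{p}.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop_config("x and y lengths differ")
  n <- length(x)
  if (n < 2L) stop_config("need n >= 2 pairs")
  d <- x - y
  s <- stats::sd(d)
  df <- n - 1L
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = df, p = 0))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement measure combining precision (Pearson correlation) with an
#' accuracy penalty for location and scale shifts:
#' \deqn{CCC = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' using biased (divide-by-n) moment estimators, as in Lin's original
#' estimator; n-1 variants differ at small n.  Its magnitude never
#' exceeds that of the Pearson correlation, with equality only when the
#' means and variances match.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, not both constant.
#' @return Concordance correlation in [-1, 1].
#' @examples
#' lins_ccc(c(1, 2, 3, 4), c(2, 3, 4, 5))  # 0.714...
#' @export
lins_ccc <- function(x, y) {
  if (length(x) != length(y)) stop_config("x and y lengths differ")
  n <- length(x)
  if (n < 3L) stop_config("need n >= 3")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 && sy2 == 0 && mx == my)
    stop_config("concordance undefined for two identical constants")
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Bland-Altman limits of agreement
#'
#' Differences \code{d = measured - predicted}; the bias is
#' \code{mean(d)} and the limits of agreement are
#' \code{bias +/- k * sd(d)} (sample SD, n-1 denominator).  Points
#' strictly outside the limits are counted.  The conventional
#' \code{k = 1.96} covers 95% of normally distributed differences.
#'
#' @param measured,predicted Paired vectors, n >= 3.
#' @param k Half-width of the limits in SD units.
#' @return List of class \code{"bland_altman"}: \code{bias},
#'   \code{sd_diff}, \code{loa_low}, \code{loa_high}, \code{n_outside},
#'   \code{pct_outside}, \code{n}, plus the per-pair \code{means} and
#'   \code{diffs} for plotting.
#' @export
bland_altman <- function(measured, predicted, k = 1.96) {
  if (length(measured) != length(predicted))
    stop_config("vectors must have equal length")
  n <- length(measured)
  if (n < 3L) stop_config("need n >= 3")
  d <- measured - predicted
  bias <- mean(d)
  s <- stats::sd(d)
  lo <- bias - k * s; hi <- bias + k * s
  out <- sum(d < lo | d > hi)
  structure(list(bias = bias, sd_diff = s, loa_low = lo, loa_high = hi,
                 n_outside = out, pct_outside = 100 * out / n, n = n, k = k,
                 means = (measured + predicted) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f, SD %.4f, LoA [%.4f, %.4f] (k = %g)\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$k))
  cat(sprintf("  %d of %d points outside (%.2f%%)\n",
              x$n_outside, x$n, x$pct_outside))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "mean of measured and predicted (BW)",
                 ylab = "measured - predicted (BW)",
                 main = "Bland-Altman", ...)
  graphics::abline(h = x$bias, lty = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 3)
  invisible(x)
}

#' Bias percentage
#'
#' Mean difference expressed relative to the mean measured value:
#' \code{mean(measured - predicted) / mean(measured) * 100}.
#'
#' @param measured,predicted Paired vectors; \code{mean(measured)} must
#'   be nonzero.
#' @return Percent bias.
#' @export
bias_percent <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop_config("vectors must have equal length")
  if (mean(measured) == 0)
    stop_config("mean of measured values is zero; percent bias undefined")
  mean(measured - predicted) / mean(measured) * 100
}

#' One-way repeated-measures ANOVA
#'
#' Classical sum-of-squares decomposition for a complete subjects x
#' conditions layout: total = subjects + conditions + error, with
#' \code{F = MS_conditions / MS_error}, \code{df1 = k - 1} and
#' \code{df2 = (k - 1)(n - 1)}.  No sphericity correction is applied.
#'
#' @param data Numeric matrix or data frame, one row per subject and one
#'   column per condition; no missing cells.
#' @return List with \code{F}, \code{df1}, \code{df2}, \code{p} and the
#'   sums of squares.
#' @export
rm_anova_oneway <- function(data) {
  m <- as.matrix(data)
  if (any(!is.finite(m))) stop_config("missing or non-finite cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop_config("need >= 2 subjects and >= 2 conditions")
  gm <- mean(m)
  ss_total <- sum((m - gm)^2)
  ss_subj <- k * sum((rowMeans(m) - gm)^2)
  ss_cond <- n * sum((colMeans(m) - gm)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  F <- if (ms_err == 0) {
    if (ms_cond == 0) 0 else Inf
  } else ms_cond / ms_err
  p <- if (F == 0) 1 else stats::pf(F, df1, df2, lower.tail = FALSE)
  list(F = F, df1 = df1, df2 = df2, p = p,
       ss = c(total = ss_total, subjects = ss_subj,
              conditions = ss_cond, error = ss_err))
}

#' Pairwise post-hoc comparisons
#'
#' Paired t-tests for every pair of conditions with multiplicity
#' adjustment (Bonferroni by default: \code{p_adj = min(1, m * p)} over
#' the m pairs).
#'
#' @param data Subjects x conditions matrix or data frame.
#' @param method Adjustment method passed to \code{\link[stats]{p.adjust}}.
#' @return Data frame with one row per condition pair: \code{t},
#'   \code{df}, \code{p} and \code{p_adj}.
#' @export
post_hoc_pairwise <- function(data, method = "bonferroni") {
  m <- as.matrix(data)
  k <- ncol(m)
  if (k < 2L) stop_config("need >= 2 conditions")
  nm <- colnames(m)
  if (is.null(nm)) nm <- paste0("C", seq_len(k))
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tt <- paired_t(m[, i1], m[, i2])
    data.frame(cond_a = nm[i1], cond_b = nm[i2],
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = method)
  out
}

#' Validation agreement battery
#'
#' Runs the full agreement analysis between force-plate-measured and
#' equation-predicted GRF on a validation set: paired t-test, Pearson
#' correlation, Lin's concordance correlation coefficient, Bland-Altman
#' bias and limits of agreement, and the bias percentage.
#'
#' @param measured Measured GRF (BW).
#' @param predicted Predicted GRF (BW).
#' @param k Bland-Altman limit half-width in SD units.
#' @return List of class \code{"agreement_report"} with elements
#'   \code{n}, \code{paired_t}, \code{pearson_r}, \code{ccc},
#'   \code{bland_altman} and \code{bias_percent}.
#' @examples
#' set.seed(1)
#' m <- rnorm(50, 0.68, 0.1); p <- m + rnorm(50, 0, 0.05)
#' agreement_report(m, p)
#' @export
agreement_report <- function(measured, predicted, k = 1.96) {
  structure(list(
    n = length(measured),
    paired_t = paired_t(predicted, measured),
    pearson_r = pearson_r(measured, predicted),
    ccc = lins_ccc(measured, predicted),
    bland_altman = bland_altman(measured, predicted, k),
    bias_percent = bias_percent(measured, predicted)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs\n", x$n))
  cat(sprintf("  paired t: t = %.3f, df = %d, p = %.3f\n",
              x$paired_t$t, x$paired_t$df, x$paired_t$p))
  cat(sprintf("  Pearson r = %.4f, Lin's CCC = %.4f\n", x$pearson_r, x$ccc))
  ba <- x$bland_altman
  cat(sprintf("  Bland-Altman bias %.4f BW, LoA [%.4f, %.4f], %.2f%% outside\n",
              ba$bias, ba$loa_low, ba$loa_high, ba$pct_outside))
  cat(sprintf("  bias percentage %.3f%%\n", x$bias_percent))
  invisible(x)
}

#' @export
plot.agreement_report <- function(x, which = c("concordance", "bland_altman"),
                                  ...) {
  which <- match.arg(which)
  if (which == "bland_altman") return(plot(x$bland_altman, ...))
  ba <- x$bland_altman
  measured <- ba$means + ba$diffs / 2
  predicted <- ba$means - ba$diffs / 2
  graphics::plot(predicted, measured, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "predicted GRF (BW)", ylab = "measured GRF (BW)",
                 main = sprintf("Concordance (CCC = %.3f)", x$ccc), ...)
  graphics::abline(0, 1, lty = 1)
  graphics::abline(stats::lm(measured ~ predicted), lty = 3)
  invisible(x)
}
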