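# Agreement statistics for paired volume estimates: ICC(2,1) with
# interpretation bands, Bland-Altman limits of agreement, and paired tests
# with a normality-driven choice between t and Wilcoxon.

#' Intraclass correlation for absolute agreement
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' (ICC(2,1)) computed from the two-way ANOVA mean squares, with the
#' McGraw-Wong 95% confidence interval and the conventional interpretation
#' bands: below 0.50 poor, 0.50-0.75 moderate, 0.75-0.90 good, above 0.90
#' excellent.
#'
#' @param pv_a,pv_b paired volume estimates (same length, >= 5 pairs).
#' @param conf confidence level for the interval.
#' @return List with `icc`, `ci` (length 2), `category`, and the ANOVA mean
#'   squares (`msr`, `msc`, `mse`).
#' @export
icc_agreement <- function(pv_a, pv_b, conf = 0.95) {
  if (length(pv_a) != length(pv_b)) stopf("paired samples differ in length")
  n <- length(pv_a)
  if (n < 5) stopf("need at least 5 pairs for ICC")
  if (any(!is.finite(pv_a)) || any(!is.finite(pv_b))) {
    stopf("non-finite values in paired volumes")
  }
  X <- cbind(pv_a, pv_b)
  k <- 2L
  row_m <- rowMeans(X)
  col_m <- colMeans(X)
  grand <- mean(X)
  if (sd(row_m) == 0) stopf("degenerate input: no between-case variance")
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  mse <- sum((X - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2) / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # McGraw & Wong CI for ICC(A,1)
  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci = c(lower, upper), category = icc_category(icc),
       msr = msr, msc = msc, mse = mse)
}

#' ICC interpretation band
#'
#' @param icc ICC estimate.
#' @return `"poor"` (< 0.50), `"moderate"` (0.50-0.75), `"good"`
#'   (0.75-0.90) or `"excellent"` (> 0.90).
#' @export
icc_category <- function(icc) {
  if (icc < 0.50) "poor"
  else if (icc <= 0.75) "moderate"
  else if (icc <= 0.90) "good"
  else "excellent"
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b` with limits of agreement at the mean difference
#' plus/minus 1.96 times the SD of the differences.
#'
#' @param pv_a,pv_b paired estimates (>= 2 pairs).
#' @param plot_file optional path; if given, a Bland-Altman plot (mean of the
#'   pair against difference) is written as PNG.
#' @return List with `mean_diff`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(pv_a, pv_b, plot_file = NULL) {
  if (length(pv_a) != length(pv_b)) stopf("paired samples differ in length")
  n <- length(pv_a)
  if (n < 2) stopf("need at least 2 pairs for Bland-Altman")
  d <- pv_a - pv_b
  m <- mean(d)
  s <- sd(d)
  out <- list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
              sd_diff = s, n = n)
  if (!is.null(plot_file)) {
    png(plot_file, width = 640, height = 480)
    plot((pv_a + pv_b) / 2, d, xlab = "mean of pair (ml)",
         ylab = "difference (ml)", main = "Bland-Altman", pch = 19)
    abline(h = m)
    abline(h = out$loa_low, lty = 2)
    abline(h = out$loa_high, lty = 2)
    dev.off()
  }
  out
}

#' Paired comparison with distribution-driven test choice
#'
#' Tests the paired differences for normality (Shapiro-Wilk at alpha 0.05);
#' if normal, a paired Student's t-test is used, otherwise a Wilcoxon
#' signed-rank test. Two-sided.
#'
#' @param x,y paired samples (equal length, n >= 5).
#' @return List with `p_value`, `test_used` (`"paired t"`,
#'   `"wilcoxon signed-rank"` or `"degenerate"`), and `shapiro_p`.
#' @export
paired_compare <- function(x, y) {
  if (length(x) != length(y)) stopf("paired samples differ in length")
  n <- length(x)
  if (n < 5) stopf("need at least 5 pairs")
  d <- x - y
  if (all(d == 0)) {
    warning("all paired differences are zero; test degenerate")
    return(list(p_value = 1, test_used = "degenerate", shapiro_p = NA_real_))
  }
  sw <- if (sd(d) > 0) shapiro.test(d)$p.value else 0
  if (sw >= 0.05) {
    p <- t.test(x, y, paired = TRUE)$p.value
    list(p_value = p, test_used = "paired t", shapiro_p = sw)
  } else {
    p <- suppressWarnings(wilcox.test(x, y, paired = TRUE)$p.value)
    list(p_value = p, test_used = "wilcoxon signed-rank", shapiro_p = sw)
  }
}
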