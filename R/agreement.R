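# Method-agreement layer: quantifies how well the sensor-based stair climb
# power tracks the stopwatch-based clinical value across subjects, and
# compares demographic groups. Differences are taken Standard minus
# sensor throughout.

#' Pearson correlation between two paired methods
#'
#' @param a,b Paired measurements (same subjects, two methods), n >= 3.
#' @return List with `r`, two-sided t-based `p`, and `n`.
#' @export
pearson_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: zero variance in one of the methods")
  }
  ct <- stats::cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement
#' intraclass correlation between two methods, computed from the two-way
#' ANOVA mean squares (subjects as rows, methods as raters):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The confidence interval uses the F-distribution method (McGraw-Wong
#' convention). When all values are identical the perfect-agreement
#' shortcut `ICC = 1` is returned.
#'
#' @param a,b Paired measurements, n >= 5 subjects.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List with `icc`, `lower`, `upper`, `n`, `k` and the mean
#'   squares `msr`, `msc`, `mse`.
#' @export
icc_2_1 <- function(a, b, conf_level = 0.95) {
  stopifnot(length(a) == length(b), length(a) >= 5)
  n <- length(a)
  k <- 2
  Y <- cbind(a, b)
  if (max(Y) - min(Y) == 0) {
    return(list(icc = 1, lower = 1, upper = 1, n = n, k = k, msr = 0, msc = 0, mse = 0))
  }
  grand <- mean(Y)
  row_m <- rowMeans(Y)
  col_m <- colMeans(Y)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  mse <- sum((Y - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2) /
    ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    lower <- upper <- 1
  } else {
    fa <- (k * icc) / (n * (1 - icc))
    fb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (fa * msc + fb * mse)^2 /
      ((fa * msc)^2 / (k - 1) + (fb * mse)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - FL * mse) /
      (FL * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (FU * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * FU * msr)
  }
  list(icc = icc, lower = lower, upper = upper, n = n, k = k,
       msr = msr, msc = msc, mse = mse)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are `d = a - b` (by convention Standard minus sensor).
#' Bias is `mean(d)`, the limits of agreement are `bias +/- 1.96 sd(d)`,
#' and confidence intervals use the standard normal-theory formulas
#' (t-quantiles; the limit standard error is `sd * sqrt(3 / n)`).
#'
#' @param a,b Paired measurements, n >= 3.
#' @param conf_level Confidence level for the intervals.
#' @return A `bland_altman` object: `bias`, `sd`, `loa_lower`,
#'   `loa_upper`, their confidence intervals, and the per-pair means and
#'   differences for plotting.
#' @export
bland_altman <- function(a, b, conf_level = 0.95) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  d <- a - b
  n <- length(d)
  bias <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(1 - (1 - conf_level) / 2, n - 1)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  structure(
    list(bias = bias, sd = s,
         loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
         ci_bias = bias + c(-1, 1) * tq * se_bias,
         ci_loa_lower = bias - 1.96 * s + c(-1, 1) * tq * se_loa,
         ci_loa_upper = bias + 1.96 * s + c(-1, 1) * tq * se_loa,
         n = n, means = (a + b) / 2, differences = d),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias = %.2f [%.2f, %.2f], LoA = [%.2f, %.2f]\n",
              x$n, x$bias, x$ci_bias[1], x$ci_bias[2], x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of methods (W)",
                              ylab = "difference (W)", ...) {
  graphics::plot(x$means, x$differences, xlab = xlab, ylab = ylab,
                 main = "Bland-Altman agreement", ...)
  graphics::abline(h = 0, col = "red3")
  graphics::abline(h = x$bias, col = "blue3")
  graphics::abline(h = c(x$loa_lower, x$loa_upper), col = "green4")
  graphics::abline(h = c(x$ci_bias, x$ci_loa_lower, x$ci_loa_upper), lty = 2,
                   col = "grey50")
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite (fractional)
#' degrees of freedom, used for age- and sex-group comparisons of power.
#'
#' @param values Numeric outcome (watts).
#' @param groups Two-level grouping vector.
#' @return List with `t`, fractional `df`, `p` and per-group means.
#' @export
welch_t_test <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2 || any(table(g) < 2)) {
    stop("protocol error: exactly two groups with n >= 2 each are required")
  }
  tt <- stats::t.test(values ~ g, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       group_means = stats::setNames(unname(tt$estimate), levels(g)))
}

#' Full method-agreement report
#'
#' Computes the agreement suite between the Standard (stopwatch) and
#' sensor-derived stair climb power of the same subjects: Pearson
#' correlation, ICC(2,1) with its confidence interval, Bland-Altman bias
#' and limits of agreement (Standard minus sensor), and optional Welch
#' t-tests of each power method across demographic groupings.
#'
#' @param standard,sensor Per-subject power values in watts (typically
#'   means across trials and visits).
#' @param groups Optional named list of grouping vectors (e.g.
#'   `list(age_group = ..., sex = ...)`) for Welch t-tests.
#' @param conf_level Confidence level.
#' @return An `scp_agreement` object.
#' @export
agreement_report <- function(standard, sensor, groups = NULL, conf_level = 0.95) {
  stopifnot(length(standard) == length(sensor), !anyNA(standard), !anyNA(sensor))
  t_tests <- NULL
  if (!is.null(groups)) {
    t_tests <- lapply(groups, function(g) {
      list(standard = welch_t_test(standard, g), sensor = welch_t_test(sensor, g))
    })
  }
  structure(
    list(pearson = pearson_correlation(standard, sensor),
         icc = icc_2_1(standard, sensor, conf_level),
         bland_altman = bland_altman(standard, sensor, conf_level),
         t_tests = t_tests, n = length(standard)),
    class = "scp_agreement"
  )
}

#' @export
print.scp_agreement <- function(x, ...) {
  cat(sprintf("<scp_agreement> n = %d subjects\n", x$n))
  cat(sprintf("  Pearson r = %.3f (p = %.2g)\n", x$pearson$r, x$pearson$p))
  cat(sprintf("  ICC(2,1) = %.3f [%.3f, %.3f]\n", x$icc$icc, x$icc$lower, x$icc$upper))
  ba <- x$bland_altman
  cat(sprintf("  Bland-Altman bias = %.2f W, LoA = [%.2f, %.2f] W\n",
              ba$bias, ba$loa_lower, ba$loa_upper))
  for (nm in names(x$t_tests)) {
    for (meth in names(x$t_tests[[nm]])) {
      tt <- x$t_tests[[nm]][[meth]]
      cat(sprintf("  %s (%s): t(%.2f) = %.2f, p = %.2g\n", nm, meth, tt$df, tt$t, tt$p))
    }
  }
  invisible(x)
}
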