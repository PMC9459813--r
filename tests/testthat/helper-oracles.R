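# Independent oracles and fixture builders shared across tests. Oracles are
# deliberately written as direct textbook formulas / brute-force loops,
# separate from the package's implementation paths.

# Pearson r by the raw sum formula
pearson_sum_formula <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# brute-force DFT magnitude-squared spectrum (no FFT)
dft_power <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    re^2 + im^2
  }, 0.0)
}

# Welch t statistic and Welch-Satterthwaite df by the textbook formulas
welch_formula <- function(x1, x2) {
  v1 <- var(x1) / length(x1)
  v2 <- var(x2) / length(x2)
  t <- (mean(x1) - mean(x2)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x1) - 1) + v2^2 / (length(x2) - 1))
  list(t = t, df = df)
}

# two-way ANOVA mean squares via stats::aov on long-format data
aov_mean_squares <- function(a, b) {
  n <- length(a)
  d <- data.frame(y = c(a, b),
                  subject = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(y ~ subject + rater, data = d))[[1]]
  list(msr = tab["subject", "Mean Sq"], msc = tab["rater", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"])
}

# literal sensor-power expression: numerator m g h4 * steps detected,
# denominator t0 plus the telescoping sum of the step intervals
literal_stairpy_power <- function(mass, h4, intervals) {
  t0 <- mean(intervals)
  steps_detected <- length(intervals) + 1
  mass * 9.81 * h4 * steps_detected / (t0 + sum(intervals))
}

# a clean 75-sample six-axis window for feature tests
make_test_window <- function(fs = 50, n = 75, fill = NULL, seed = 1) {
  set.seed(seed)
  mk <- function() if (is.null(fill)) rnorm(n) else rep(fill, n)
  structure(
    list(accel = cbind(x = mk(), y = mk(), z = mk()),
         gyro = cbind(x = mk(), y = mk(), z = mk()),
         fs = fs, label = "gait", start_time = 0,
         subject_id = "S01", visit_id = "V1", task_id = "T1"),
    class = "segment_window"
  )
}

# toy labeled dataset with explicit structure
make_toy_dataset <- function(x, y, subject, visit = rep("V1", length(y)),
                             task = rep("T1", length(y)), positive = levels(y)[2]) {
  structure(
    list(x = as.matrix(x), y = y, positive = positive, subject = subject,
         visit = visit, task_id = task),
    class = "labeled_dataset"
  )
}
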