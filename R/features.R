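# Windowed signal features for activity classification. The fixed per-axis
# set (23 features) plus 3 cross-axis correlations gives 72 features per
# sensor; the accelerometer additionally contributes per-axis signal range
# and a vertical-axis step-band wavelet energy, for 76, hence 148 combined.

axis_feature_set <- c(
  "mean", "min", "max", "median", "var", "std", "rms", "skew", "kurt",
  "hist_entropy", "spec_entropy", "autocorr1", "dom_freq", "fft_energy",
  "p05", "p20", "p25", "p75", "p80", "p95", "iqr", "mad", "zero_cross"
)

#' Canonical feature names
#'
#' The fixed, ordered feature vocabulary: per sensor and axis the 23-item
#' statistical/spectral set, then the three pairwise cross-axis Pearson
#' correlations; the accelerometer block appends per-axis range and the
#' vertical step-band wavelet energy. Accelerometer features come first.
#'
#' @param sensor_set `"accel"`, `"gyro"` or `"both"`.
#' @return Character vector of length 76, 72 or 148.
#' @examples
#' length(feature_names("both"))   # 148
#' length(feature_names("accel"))  # 76
#' @export
feature_names <- function(sensor_set = c("both", "accel", "gyro")) {
  sensor_set <- match.arg(sensor_set)
  sensors <- switch(sensor_set, both = c("accel", "gyro"), accel = "accel", gyro = "gyro")
  unlist(lapply(sensors, function(sensor) {
    base <- c(
      as.vector(t(outer(c("x", "y", "z"), axis_feature_set,
                        function(ax, f) paste(sensor, ax, f, sep = "_")))),
      paste0(sensor, "_", c("xy", "xz", "yz"), "_corr")
    )
    if (sensor == "accel") {
      base <- c(base, paste0("accel_", c("x", "y", "z"), "_range"),
                "accel_x_stepband_energy")
    }
    base
  }), use.names = FALSE)
}

#' Histogram (amplitude) entropy of a signal
#'
#' Shannon entropy, in bits, of the 10-equal-width-bin amplitude histogram
#' over `[min(x), max(x)]`, maximum inclusive in the last bin. A
#' zero-variance input has zero entropy by convention.
#'
#' @param x Numeric vector, length >= 2.
#' @param n_bins Number of equal-width bins (default 10).
#' @return Entropy in bits, in `[0, log2(n_bins)]`.
#' @examples
#' histogram_entropy(seq_len(100))  # log2(10): every bin holds 10 points
#' @export
histogram_entropy <- function(x, n_bins = 10) {
  stopifnot(length(x) >= 2)
  r <- range(x)
  if (diff(r) == 0) return(0)
  breaks <- seq(r[1], r[2], length.out = n_bins + 1)
  cnt <- table(cut(x, breaks, include.lowest = TRUE, right = FALSE))
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p))
}

#' Lag-1 autocorrelation
#'
#' Pearson correlation of `(x[1..n-1], x[2..n])`; defined as 0 when either
#' shifted copy has zero variance.
#'
#' @param x Numeric vector, length >= 3.
#' @return Value in `[-1, 1]`.
#' @export
lag1_autocorrelation <- function(x) {
  stopifnot(length(x) >= 3)
  a <- x[-length(x)]
  b <- x[-1]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Non-DC FFT energy and dominant frequency
#'
#' `fft_energy()` is the sum of squared magnitudes of all non-DC discrete
#' Fourier bins divided by the window length; a constant signal therefore
#' has zero energy. `dominant_frequency()` is the frequency of the largest
#' non-DC bin in the first half-spectrum (0 for a spectrally empty signal).
#'
#' @param x Numeric vector, length >= 4.
#' @param fs Sampling rate in Hz.
#' @return A scalar: energy in squared signal units, or frequency in Hz.
#' @export
fft_energy <- function(x) {
  stopifnot(length(x) >= 4)
  X <- stats::fft(x)
  sum(Mod(X[-1])^2) / length(x)
}

#' @rdname fft_energy
#' @export
dominant_frequency <- function(x, fs) {
  stopifnot(length(x) >= 4, fs > 0)
  if (stats::sd(x) == 0) return(0)  # spectrally empty by convention
  n <- length(x)
  X <- Mod(stats::fft(x))[2:(floor(n / 2) + 1)]
  if (max(X) == 0) return(0)
  which.max(X) * fs / n
}

# Shannon entropy (bits) of the normalised non-DC half-spectrum power.
spectral_entropy <- function(x) {
  if (stats::sd(x) == 0) return(0)
  n <- length(x)
  P <- Mod(stats::fft(x))[2:(floor(n / 2) + 1)]^2
  s <- sum(P)
  if (s == 0) return(0)
  p <- P[P > 0] / s
  -sum(p * log2(p))
}

#' Step-band wavelet energy of the vertical acceleration
#'
#' Mean squared response of the continuous Gaussian-derivative wavelet at
#' the scale whose peak frequency response sits at the stair-stepping band
#' (0.5 s pseudo-period, i.e. 2 Hz). Quadratic in signal amplitude; favours
#' step-rate oscillations over high-frequency content. A stand-in for the
#' wavelet-derived stair-climbing measures of the activity-recognition
#' literature, with the same intent.
#'
#' @param x_vertical Vertical acceleration in m/s^2.
#' @param fs Sampling rate in Hz.
#' @param scale_s Wavelet pseudo-period in seconds (default 0.5).
#' @return Energy in (m/s^2)^2.
#' @export
stepband_wavelet_energy <- function(x_vertical, fs, scale_s = 0.5) {
  w <- cwt_gauss_deriv(x_vertical - mean(x_vertical), fs, scale_s)
  sum(w^2) / length(w)
}

# the 23 per-axis features, in canonical order
axis_features <- function(x, fs) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  q <- unname(stats::quantile(x, c(0.05, 0.20, 0.25, 0.75, 0.80, 0.95)))
  vals <- c(
    mean = m,
    min = min(x),
    max = max(x),
    median = stats::median(x),
    var = stats::var(x),
    std = stats::sd(x),
    rms = sqrt(mean(x^2)),
    skew = if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0,
    kurt = if (m2 > 0) mean((x - m)^4) / m2^2 - 3 else 0,
    hist_entropy = histogram_entropy(x),
    spec_entropy = spectral_entropy(x),
    autocorr1 = lag1_autocorrelation(x),
    dom_freq = dominant_frequency(x, fs),
    fft_energy = fft_energy(x),
    p05 = q[1], p20 = q[2], p25 = q[3], p75 = q[4], p80 = q[5], p95 = q[6],
    iqr = q[4] - q[3],
    mad = mean(abs(x - m)),
    zero_cross = sum(x[-1] * x[-n] < 0)
  )
  vals
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

sensor_block <- function(mat, fs, sensor) {
  out <- c(
    unlist(lapply(1:3, function(j) {
      v <- axis_features(mat[, j], fs)
      names(v) <- paste(sensor, c("x", "y", "z")[j], names(v), sep = "_")
      v
    })),
    stats::setNames(
      c(safe_cor(mat[, 1], mat[, 2]), safe_cor(mat[, 1], mat[, 3]),
        safe_cor(mat[, 2], mat[, 3])),
      paste0(sensor, "_", c("xy", "xz", "yz"), "_corr")
    )
  )
  out
}

#' Extract the windowed feature vector
#'
#' Computes the fixed named feature set from one segment window: 76
#' accelerometer features, 72 gyroscope features, or all 148. Windows are
#' not re-detrended, so orientation/gravity content (e.g. the vertical
#' accelerometer mean) is deliberately retained as a feature.
#'
#' @param win A `segment_window` from [make_windows()].
#' @param sensor_set `"accel"`, `"gyro"` or `"both"` (default: `"both"`
#'   when the window has gyroscope channels, else `"accel"`).
#' @return Named numeric vector in the [feature_names()] order, all finite.
#' @export
extract_features <- function(win, sensor_set = NULL) {
  stopifnot(inherits(win, "segment_window"))
  if (is.null(sensor_set)) sensor_set <- if (is.null(win$gyro)) "accel" else "both"
  sensor_set <- match.arg(sensor_set, c("both", "accel", "gyro"))
  if (sensor_set %in% c("both", "gyro") && is.null(win$gyro)) {
    stop("sensor_set '", sensor_set, "' requested but the window has no gyroscope channels")
  }
  out <- numeric(0)
  if (sensor_set %in% c("both", "accel")) {
    ab <- sensor_block(win$accel, win$fs, "accel")
    extras <- c(
      stats::setNames(apply(win$accel, 2, function(v) diff(range(v))),
                      paste0("accel_", c("x", "y", "z"), "_range")),
      accel_x_stepband_energy = stepband_wavelet_energy(win$accel[, 1], win$fs)
    )
    out <- c(out, ab, extras)
  }
  if (sensor_set %in% c("both", "gyro")) {
    out <- c(out, sensor_block(win$gyro, win$fs, "gyro"))
  }
  out <- out[feature_names(sensor_set)]
  stopifnot(all(is.finite(out)))
  out
}

#' Build a feature matrix from a list of windows
#'
#' One row per window: provenance columns (`subject_id`, `visit_id`,
#' `task_id`, `label`, `start_time`) followed by the features in canonical
#' order.
#'
#' @param windows List of `segment_window` objects.
#' @param sensor_set Passed to [extract_features()].
#' @return A `data.frame`.
#' @export
extract_feature_matrix <- function(windows, sensor_set = NULL) {
  stopifnot(length(windows) > 0)
  rows <- lapply(windows, function(w) {
    f <- extract_features(w, sensor_set)
    cbind(
      data.frame(subject_id = w$subject_id, visit_id = w$visit_id,
                 task_id = w$task_id, label = w$label, start_time = w$start_time,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(f), check.names = FALSE)
    )
  })
  do.call(rbind, rows)
}
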