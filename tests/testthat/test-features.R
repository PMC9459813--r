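test_that("feature vectors have the fixed counts and canonical finite values", {
  win <- make_test_window()
  both <- extract_features(win, "both")
  accel <- extract_features(win, "accel")
  gyro <- extract_features(win, "gyro")
  expect_length(both, 148)
  expect_length(accel, 76)
  expect_length(gyro, 72)
  expect_identical(names(both), feature_names("both"))
  expect_identical(names(accel), feature_names("accel"))
  expect_true(all(is.finite(both)))
  # accel-only window cannot provide gyro features
  win$gyro <- NULL
  expect_length(extract_features(win), 76)
  expect_error(extract_features(win, "both"), "no gyroscope channels")
})

test_that("a constant window collapses to the degenerate feature values", {
  win <- make_test_window(fill = 4.2)
  f <- extract_features(win, "both")
  expect_equal(unname(f["accel_x_mean"]), 4.2)
  expect_equal(unname(f["accel_x_range"]), 0)
  expect_equal(unname(f["accel_y_var"]), 0)
  expect_equal(unname(f["accel_z_hist_entropy"]), 0)
  expect_equal(unname(f["gyro_x_zero_cross"]), 0)
  expect_equal(unname(f["gyro_y_autocorr1"]), 0)
  expect_equal(unname(f["accel_xy_corr"]), 0)
  expect_equal(unname(f["accel_x_fft_energy"]), 0)
  expect_equal(unname(f["accel_x_dom_freq"]), 0)
})

test_that("a 2 Hz unit sine has dominant frequency 2 Hz and RMS 1/sqrt(2)", {
  t <- (0:74) / 50
  win <- make_test_window()
  win$accel[, "x"] <- sin(2 * pi * 2 * t)
  f <- extract_features(win, "accel")
  expect_lt(abs(f[["accel_x_dom_freq"]] - 2), 50 / 75 + 1e-12)
  expect_equal(f[["accel_x_rms"]], 1 / sqrt(2), tolerance = 1e-9)
})

test_that("histogram entropy matches its closed-form cases", {
  expect_equal(histogram_entropy(rep(3, 10)), 0)
  expect_equal(histogram_entropy(seq(0, 99)), log2(10), tolerance = 1e-12)
  expect_equal(histogram_entropy(rep(c(0, 1), each = 50)), 1.0, tolerance = 1e-12)
})

test_that("lag-1 autocorrelation agrees with the brute-force shifted-copy formula", {
  expect_equal(lag1_autocorrelation(rep(1, 10)), 0)
  alt <- rep(c(1, -1), length.out = 75)
  expect_equal(lag1_autocorrelation(alt), pearson_sum_formula(alt[-75], alt[-1]),
               tolerance = 1e-12)
  expect_lt(lag1_autocorrelation(alt), -0.99)
  ramp <- as.numeric(1:75)
  expect_equal(lag1_autocorrelation(ramp), pearson_sum_formula(ramp[-75], ramp[-1]),
               tolerance = 1e-12)
  expect_gt(lag1_autocorrelation(ramp), 0.99)
})

test_that("FFT energy matches a brute-force DFT oracle and excludes DC", {
  expect_equal(fft_energy(rep(0, 75)), 0)
  expect_equal(fft_energy(rep(5, 75)), 0, tolerance = 1e-18)
  x <- sin(2 * pi * 2 * (0:74) / 50)
  p <- dft_power(x)
  expect_equal(fft_energy(x), sum(p[-1]) / 75, tolerance = 1e-9)
  expect_equal(dominant_frequency(x, 50), (which.max(p[2:38])) * 50 / 75)
})

test_that("step-band wavelet energy is quadratic in amplitude and favours the 2 Hz band", {
  t <- (0:74) / 50
  s2 <- sin(2 * pi * 2 * t)
  expect_equal(stepband_wavelet_energy(rep(0, 75), 50), 0)
  expect_equal(stepband_wavelet_energy(2 * s2, 50),
               4 * stepband_wavelet_energy(s2, 50), tolerance = 1e-9)
  s10 <- sin(2 * pi * 10 * t)
  expect_gt(stepband_wavelet_energy(s2, 50), stepband_wavelet_energy(s10, 50))
})

test_that("features obey amplitude-scale equivariance", {
  scale_linear <- paste0("accel_x_", c("mean", "min", "max", "median", "std", "rms",
                                       "p05", "p20", "p25", "p75", "p80", "p95",
                                       "iqr", "mad", "range"))
  scale_quadratic <- paste0("accel_x_", c("var", "fft_energy", "stepband_energy"))
  invariant <- c(paste0("accel_x_", c("skew", "kurt", "hist_entropy", "spec_entropy",
                                      "autocorr1", "dom_freq", "zero_cross")),
                 "accel_xy_corr", "gyro_yz_corr")
  for (seed in 1:5) {
    win <- make_test_window(seed = seed)
    a <- runif(1, 0.5, 3)
    win2 <- win
    win2$accel <- a * win$accel
    win2$gyro <- a * win$gyro
    f1 <- extract_features(win, "both")
    f2 <- extract_features(win2, "both")
    expect_equal(f2[scale_linear], a * f1[scale_linear], tolerance = 1e-9)
    expect_equal(f2[scale_quadratic], a^2 * f1[scale_quadratic], tolerance = 1e-9)
    expect_equal(f2[invariant], f1[invariant], tolerance = 1e-9)
  }
})

test_that("swapping the y and z channels swaps the corresponding feature values", {
  win <- make_test_window(seed = 11)
  sw <- win
  sw$accel <- win$accel[, c(1, 3, 2)]
  sw$gyro <- win$gyro[, c(1, 3, 2)]
  colnames(sw$accel) <- colnames(sw$gyro) <- c("x", "y", "z")
  f <- extract_features(win, "both")
  g <- extract_features(sw, "both")
  expect_identical(unname(g["accel_y_mean"]), unname(f["accel_z_mean"]))
  expect_identical(unname(g["gyro_z_var"]), unname(f["gyro_y_var"]))
  expect_identical(unname(g["accel_y_range"]), unname(f["accel_z_range"]))
  expect_identical(unname(g["accel_xy_corr"]), unname(f["accel_xz_corr"]))
  expect_identical(unname(g["gyro_yz_corr"]), unname(f["gyro_yz_corr"]))
  expect_identical(unname(g["accel_x_stepband_energy"]), unname(f["accel_x_stepband_energy"]))
})

test_that("the feature matrix carries provenance columns first", {
  rec <- imu_recording(accel = matrix(rnorm(200 * 3), ncol = 3),
                       gyro = matrix(rnorm(200 * 3), ncol = 3), fs = 50,
                       subject_id = "S01", visit_id = "V1")
  fm <- extract_feature_matrix(make_windows(rec, "gait", task_id = "gait_T1"))
  expect_identical(names(fm)[1:5],
                   c("subject_id", "visit_id", "task_id", "label", "start_time"))
  expect_identical(names(fm)[-(1:5)], feature_names("both"))
  expect_equal(nrow(fm), 4)
})
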