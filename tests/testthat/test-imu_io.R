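test_that("reading a 7-column CSV yields a validated recording with the right duration", {
  rec0 <- imu_recording(accel = matrix(rnorm(512 * 3), ncol = 3),
                        gyro = matrix(rnorm(512 * 3), ncol = 3), fs = 128)
  f <- tempfile(fileext = ".csv")
  write_imu_csv(rec0, f)
  rec <- read_imu_csv(f, fs = 128)
  expect_s3_class(rec, "imu_recording")
  expect_equal(n_samples(rec), 512)
  expect_equal(imu_duration(rec), 511 / 128)  # 3.9921875 s
  expect_false(is.null(rec$gyro))
})

test_that("write/read round trip reproduces channels within 1e-9 and metadata", {
  rec0 <- imu_recording(accel = matrix(rnorm(100 * 3, sd = 5), ncol = 3),
                        gyro = matrix(rnorm(100 * 3), ncol = 3), fs = 128,
                        subject_id = "S07", visit_id = "V2")
  f <- tempfile(fileext = ".csv")
  write_imu_csv(rec0, f)
  rec <- read_imu_csv(f, fs = 128, subject_id = "S07", visit_id = "V2")
  expect_lt(max(abs(rec$accel - rec0$accel)), 1e-9)
  expect_lt(max(abs(rec$gyro - rec0$gyro)), 1e-9)
  expect_identical(rec$subject_id, "S07")
  expect_identical(rec$fs, 128)
})

test_that("a CSV without gyro columns loads in accelerometer-only mode", {
  d <- data.frame(t = (0:99) / 50, ax = rnorm(100), ay = rnorm(100), az = rnorm(100))
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  rec <- read_imu_csv(f, fs = 50)
  expect_null(rec$gyro)
})

test_that("g-unit input is converted to m/s^2", {
  d <- data.frame(t = (0:9) / 50, ax = 1, ay = 0, az = 0)
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  rec <- read_imu_csv(f, fs = 50, units = "g")
  expect_equal(unname(rec$accel[1, 1]), 9.81)
})

test_that("duplicated or irregular timestamps raise a sampling error naming the index", {
  d <- data.frame(t = c(0, 1, 1, 2) / 50, ax = rnorm(4), ay = rnorm(4), az = rnorm(4))
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  expect_error(read_imu_csv(f, fs = 50), "non-uniform sampling.*samples 2 and 3")
})

test_that("a missing required column is a format error", {
  d <- data.frame(t = (0:9) / 50, ax = rnorm(10), ay = rnorm(10))
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  expect_error(read_imu_csv(f, fs = 50), "malformed header.*az")
})

test_that("resampling 512 samples at 128 Hz to 50 Hz yields 200 samples", {
  rec <- imu_recording(accel = matrix(rnorm(512 * 3), ncol = 3), fs = 128)
  out <- resample_recording(rec, 50)
  expect_equal(n_samples(out), 200)
  expect_equal(out$fs, 50)
  expect_lt(abs(imu_duration(out) - imu_duration(rec)), 1 / 50)
})

test_that("resampling preserves a constant channel to 1e-9 and rejects upsampling", {
  rec <- imu_recording(accel = matrix(7.3, 512, 3), fs = 128)
  out <- resample_recording(rec, 50)
  expect_lt(max(abs(out$accel - 7.3)), 1e-9)
  expect_error(resample_recording(rec, 200), "upsampling not supported")
})

test_that("a 2 Hz sine resampled from 128 to 50 Hz keeps its dominant frequency", {
  t <- (0:1023) / 128
  rec <- imu_recording(accel = cbind(sin(2 * pi * 2 * t), 0 * t, 0 * t), fs = 128)
  out <- resample_recording(rec, 50)
  n <- n_samples(out)
  expect_lt(abs(dominant_frequency(out$accel[, 1], 50) - 2), 50 / n + 1e-12)
})

test_that("chained resampling 128->100->50 matches direct 128->50 on band-limited input", {
  t <- (0:1023) / 128
  x <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 7 * t + 0.3) + 0.3 * sin(2 * pi * 9.5 * t + 1)
  rec <- imu_recording(accel = cbind(x, x / 2, -x), fs = 128)
  a <- resample_recording(resample_recording(rec, 100), 50)
  b <- resample_recording(rec, 50)
  rms <- sqrt(mean((a$accel - b$accel)^2))
  expect_lt(rms, 1e-6)
})

test_that("annotation slicing uses half-open intervals and checks bounds", {
  rec <- imu_recording(accel = matrix(rnorm(500 * 3), ncol = 3), fs = 50)
  ann <- data.frame(start = 2, end = 6, label = "ascent", task_id = "T1")
  sl <- slice_by_annotation(rec, ann)
  expect_equal(n_samples(sl), 200)
  expect_equal(sl$time[1], 0)  # re-based time grid
  # identity slice over the full half-open span
  full <- slice_recording(rec, 0, n_samples(rec) / rec$fs)
  expect_equal(full$accel, rec$accel)
  expect_error(slice_recording(rec, 8, 12), "outside recording span")
})

test_that("annotation files are validated", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(start = 0, end = 2, label = "ascent", task_id = "T1"), f,
            row.names = FALSE)
  ann <- read_annotations(f)
  expect_equal(ann$label, "ascent")
  write.csv(data.frame(start = 0, end = 2, label = "jumping", task_id = "T1"), f,
            row.names = FALSE)
  expect_error(read_annotations(f), "labels must be one of")
  write.csv(data.frame(start = 2, end = 2, label = "gait", task_id = "T1"), f,
            row.names = FALSE)
  expect_error(read_annotations(f), "end > start")
})
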