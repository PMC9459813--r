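#' Construct a six-axis lumbar IMU recording
#'
#' An `imu_recording` holds a uniformly sampled triaxial accelerometer
#' signal (m/s^2) and, optionally, a triaxial gyroscope signal (rad/s) from
#' a sensor worn on the lower back. Axis convention: x = vertical
#' (gravity-inclusive), y = medial-lateral, z = anterior-posterior.
#' Sample `i` (1-based) is at time `(i - 1) / fs` seconds.
#'
#' @param accel Numeric matrix with `n >= 2` rows and columns `x`, `y`, `z`
#'   (vertical, medial-lateral, anterior-posterior), in m/s^2.
#' @param fs Sampling rate in Hz (> 0).
#' @param gyro Optional numeric matrix, same shape as `accel`, in rad/s.
#'   `NULL` marks an accelerometer-only recording.
#' @param time Optional time vector in seconds; defaults to `(0:(n-1))/fs`.
#'   Must be uniform at `1/fs` within `1e-6 / fs`.
#' @param subject_id,visit_id Opaque provenance labels.
#' @return An object of class `imu_recording`.
#' @examples
#' rec <- imu_recording(accel = matrix(rnorm(300), ncol = 3,
#'                                     dimnames = list(NULL, c("x", "y", "z"))),
#'                      fs = 50)
#' rec
#' @export
imu_recording <- function(accel, fs, gyro = NULL, time = NULL,
                          subject_id = NA_character_, visit_id = NA_character_) {
  accel <- as.matrix(accel)
  if (ncol(accel) != 3) stop("accel must have 3 columns (x, y, z)")
  colnames(accel) <- c("x", "y", "z")
  n <- nrow(accel)
  if (n < 2) stop("recording must contain at least 2 samples")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  if (!is.null(gyro)) {
    gyro <- as.matrix(gyro)
    if (nrow(gyro) != n || ncol(gyro) != 3) stop("gyro must match accel dimensions")
    colnames(gyro) <- c("x", "y", "z")
  }
  if (is.null(time)) time <- (0:(n - 1)) / fs
  if (length(time) != n) stop("time must match the number of samples")
  check_uniform_time(time, fs)
  structure(
    list(time = as.numeric(time), accel = accel, gyro = gyro, fs = fs,
         subject_id = subject_id, visit_id = visit_id),
    class = "imu_recording"
  )
}

check_uniform_time <- function(time, fs) {
  dt <- diff(time)
  bad <- which(abs(dt - 1 / fs) >= 1e-6 / fs)
  if (length(bad)) {
    stop(sprintf(
      "non-uniform sampling: interval between samples %d and %d is %.9g s, expected %.9g s",
      bad[1], bad[1] + 1, dt[bad[1]], 1 / fs
    ))
  }
  invisible(TRUE)
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording> %d samples @ %g Hz (%.4f s), %s%s\n",
    n_samples(x), x$fs, imu_duration(x),
    if (is.null(x$gyro)) "accelerometer only" else "accelerometer + gyroscope",
    if (!is.na(x$subject_id)) paste0(", subject ", x$subject_id) else ""
  ))
  invisible(x)
}

#' Number of samples and duration of a recording
#'
#' `imu_duration()` is the elapsed time between the first and last sample,
#' `(n - 1) / fs` seconds.
#' @param rec An `imu_recording`.
#' @return A scalar.
#' @export
n_samples <- function(rec) nrow(rec$accel)

#' @rdname n_samples
#' @export
imu_duration <- function(rec) (n_samples(rec) - 1) / rec$fs

#' @export
as.data.frame.imu_recording <- function(x, ...) {
  d <- data.frame(t = x$time, ax = x$accel[, 1], ay = x$accel[, 2], az = x$accel[, 3])
  if (!is.null(x$gyro)) {
    d$gx <- x$gyro[, 1]
    d$gy <- x$gyro[, 2]
    d$gz <- x$gyro[, 3]
  }
  d
}

#' Read an IMU recording from delimited text
#'
#' Expects a header row with columns `t, ax, ay, az` and optionally
#' `gx, gy, gz`; a file without gyroscope columns yields an
#' accelerometer-only recording. Acceleration may be supplied in m/s^2
#' (`units = "ms2"`, the native unit) or in g (`units = "g"`, converted by
#' 9.81).
#'
#' @param path Path to a delimited text file (comma-separated by default).
#' @param fs Sampling rate in Hz; if `NULL`, inferred from the median time
#'   step. The time column must be uniform at `1/fs`.
#' @param units `"ms2"` or `"g"` for the accelerometer columns.
#' @param sep Field separator.
#' @param subject_id,visit_id Provenance labels attached to the recording.
#' @return An `imu_recording`.
#' @seealso [write_imu_csv()], [resample_recording()]
#' @export
read_imu_csv <- function(path, fs = NULL, units = c("ms2", "g"), sep = ",",
                         subject_id = NA_character_, visit_id = NA_character_) {
  units <- match.arg(units)
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = TRUE)
  need <- c("t", "ax", "ay", "az")
  if (!all(need %in% names(d))) {
    stop("malformed header: required columns ", paste(setdiff(need, names(d)), collapse = ", "),
         " missing in ", path)
  }
  gcols <- c("gx", "gy", "gz")
  has_gyro <- all(gcols %in% names(d))
  scale <- if (units == "g") 9.81 else 1
  accel <- as.matrix(d[, c("ax", "ay", "az")]) * scale
  gyro <- if (has_gyro) as.matrix(d[, gcols]) else NULL
  if (is.null(fs)) {
    dt <- stats::median(diff(d$t))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate from time column")
    fs <- 1 / dt
  }
  imu_recording(accel = accel, fs = fs, gyro = gyro, time = d$t,
                subject_id = subject_id, visit_id = visit_id)
}

#' Write an IMU recording to delimited text
#'
#' Values are written with 17 significant digits so a read/write round trip
#' reproduces every channel to full double precision.
#'
#' @param rec An `imu_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  d <- as.data.frame(rec)
  fmt <- vapply(d, function(col) sprintf("%.17g", col), character(nrow(d)))
  out <- rbind(colnames(d), fmt)
  writeLines(apply(out, 1, paste, collapse = ","), path)
  invisible(path)
}

#' Read or build event annotations
#'
#' Annotations label half-open time intervals `[start, end)` of a recording
#' with an activity: `ascent`, `descent` or `gait`.
#'
#' @param path CSV file with columns `start, end, label, task_id`.
#' @return A `data.frame` with those four columns, validated.
#' @export
read_annotations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "label", "task_id")
  if (!all(need %in% names(d))) {
    stop("malformed annotation header: need columns ", paste(need, collapse = ", "))
  }
  validate_annotations(d[, need])
}

activity_levels <- c("ascent", "descent", "gait")

validate_annotations <- function(d) {
  if (any(!d$label %in% activity_levels)) {
    stop("annotation labels must be one of: ", paste(activity_levels, collapse = ", "))
  }
  if (any(d$end <= d$start)) stop("annotation intervals must satisfy end > start")
  d
}

#' Resample a recording to a lower rate
#'
#' Anti-aliased zero-phase resampling: each channel is extended by Burg
#' linear prediction to suppress edge transients, low-pass filtered with a
#' zero-phase order-8 Butterworth at 90% of the target Nyquist frequency,
#' and interpolated onto the target grid with a Kaiser-windowed sinc
#' kernel. Duration is preserved within one output sample.
#'
#' @param rec An `imu_recording`.
#' @param target_fs Target rate in Hz, `<= rec$fs`.
#' @return An `imu_recording` at `target_fs`.
#' @examples
#' rec <- imu_recording(matrix(rnorm(512 * 3), ncol = 3), fs = 128)
#' rec50 <- resample_recording(rec, 50)
#' n_samples(rec50)  # 200
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "imu_recording"))
  if (target_fs > rec$fs) {
    stop("upsampling not supported: target_fs (", target_fs, " Hz) exceeds recording rate (",
         rec$fs, " Hz)")
  }
  if (target_fs == rec$fs) return(rec)
  accel <- apply(rec$accel, 2, resample_channel, fs = rec$fs, target_fs = target_fs)
  gyro <- if (!is.null(rec$gyro)) {
    apply(rec$gyro, 2, resample_channel, fs = rec$fs, target_fs = target_fs)
  }
  imu_recording(accel = accel, fs = target_fs, gyro = gyro,
                subject_id = rec$subject_id, visit_id = rec$visit_id)
}

#' Slice a recording by a time interval or annotation
#'
#' Returns the samples with `start <= t < end` (half-open, so windows of
#' abutting annotations never share a sample). The interval must lie within
#' `[0, n / fs)`; with the half-open convention `end` may extend one sample
#' period past the last sample time.
#'
#' @param rec An `imu_recording`.
#' @param start,end Interval bounds in seconds.
#' @return An `imu_recording` covering the interval.
#' @export
slice_recording <- function(rec, start, end) {
  stopifnot(inherits(rec, "imu_recording"))
  if (end <= start) stop("slice requires end > start")
  span_end <- n_samples(rec) / rec$fs
  if (start < rec$time[1] - 1e-9 || end > span_end + 1e-9) {
    stop(sprintf("slice [%g, %g) outside recording span [%g, %g)",
                 start, end, rec$time[1], span_end))
  }
  keep <- rec$time >= start - 1e-9 & rec$time < end - 1e-9
  if (!any(keep)) stop("slice contains no samples")
  imu_recording(accel = rec$accel[keep, , drop = FALSE], fs = rec$fs,
                gyro = if (!is.null(rec$gyro)) rec$gyro[keep, , drop = FALSE],
                subject_id = rec$subject_id, visit_id = rec$visit_id)
}

#' @rdname slice_recording
#' @param ann One-row annotation (`data.frame` with `start`, `end`).
#' @export
slice_by_annotation <- function(rec, ann) {
  stopifnot(is.data.frame(ann), nrow(ann) == 1)
  slice_recording(rec, ann$start, ann$end)
}
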