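#' Cut a labeled recording into fixed sliding windows
#'
#' Segments a recording into windows of `window_s` seconds with fractional
#' `overlap`, the canonical pre-processing for windowed activity
#' classification. The window length is `W = round(window_s * fs)` samples
#' and the hop is `H = floor(W * (1 - overlap))` samples (the floor keeps
#' the realised overlap at least the requested one when `W * overlap` is
#' fractional, e.g. 75-sample windows at 50 Hz hop by 37). Windows start at
#' samples `0, H, 2H, ...`; a trailing partial window is discarded.
#'
#' Windowing is applied per recording, so windows never straddle the
#' boundary of the annotated event the recording was sliced from and each
#' window inherits a single activity label.
#'
#' @param rec An [imu_recording()], typically one sliced activity event.
#' @param label Activity label for every window: `"ascent"`, `"descent"`
#'   or `"gait"`.
#' @param window_s Window length in seconds (default 1.5).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @param task_id Provenance label for the source event.
#' @return A list of `segment_window` objects (possibly empty, with a
#'   warning, when the recording is shorter than one window). Each window
#'   carries `accel`, `gyro` (or `NULL`), `fs`, `label`, `start_time` and
#'   `subject_id` / `visit_id` / `task_id` provenance.
#' @examples
#' rec <- imu_recording(matrix(rnorm(600), ncol = 3), fs = 50)
#' length(make_windows(rec, "gait"))  # floor((200 - 75) / 37) + 1 = 4
#' @export
make_windows <- function(rec, label, window_s = 1.5, overlap = 0.5,
                         task_id = NA_character_) {
  stopifnot(inherits(rec, "imu_recording"))
  label <- match.arg(label, activity_levels)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (window_s <= 0) stop("window_s must be positive")
  W <- round(window_s * rec$fs)
  H <- max(1L, floor(W * (1 - overlap)))
  N <- n_samples(rec)
  if (N < W) {
    warning(sprintf("recording (%d samples) shorter than one %d-sample window; no windows produced",
                    N, W))
    return(list())
  }
  starts <- seq(0L, N - W, by = H)
  lapply(starts, function(s0) {
    idx <- (s0 + 1):(s0 + W)
    structure(
      list(
        accel = rec$accel[idx, , drop = FALSE],
        gyro = if (!is.null(rec$gyro)) rec$gyro[idx, , drop = FALSE],
        fs = rec$fs,
        label = label,
        start_time = rec$time[s0 + 1],
        subject_id = rec$subject_id,
        visit_id = rec$visit_id,
        task_id = task_id
      ),
      class = "segment_window"
    )
  })
}

#' @export
print.segment_window <- function(x, ...) {
  cat(sprintf("<segment_window> %s, %d samples @ %g Hz, start %.3f s (subject %s, task %s)\n",
              x$label, nrow(x$accel), x$fs, x$start_time, x$subject_id, x$task_id))
  invisible(x)
}
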