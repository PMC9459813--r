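#' Detector configuration
#'
#' Tunable constants of the initial-contact detector. The wavelet scales
#' are pseudo-periods in seconds (see [cwt_gauss_deriv()]). Defaults:
#' order-4 low-pass Butterworth at 5 Hz (stair-stepping content at a
#' natural pace lies below 5 Hz), detrend by subtracting a Gaussian-smooth
#' component at 1.5 s scale, Gaussian-derivative wavelet at 0.35 s scale,
#' minimum peak separation 0.3 s, peak prominence threshold 0.5 times the
#' standard deviation of the transformed signal, and the 1.2 s
#' misdetection threshold on inter-step intervals.
#'
#' @param lowpass_cutoff Low-pass cutoff in Hz.
#' @param lowpass_order Butterworth order (applied zero-phase).
#' @param detrend_scale_s Scale of the Gaussian-smooth trend removed before
#'   filtering, in seconds.
#' @param cwt_scale_s Gaussian-derivative wavelet scale, in seconds.
#' @param min_peak_separation Minimum spacing between detected contacts,
#'   in seconds; must be below `max_interval_s`.
#' @param peak_prominence_frac Prominence threshold as a fraction of the
#'   transformed signal's standard deviation.
#' @param max_interval_s Misdetection threshold on inter-step intervals,
#'   in seconds (default 1.2): longer intervals are flagged invalid.
#' @return A `detector_config` list.
#' @export
detector_config <- function(lowpass_cutoff = 5, lowpass_order = 4,
                            detrend_scale_s = 1.5, cwt_scale_s = 0.35,
                            min_peak_separation = 0.3,
                            peak_prominence_frac = 0.5,
                            max_interval_s = 1.2) {
  cfg <- list(
    lowpass_cutoff = lowpass_cutoff, lowpass_order = lowpass_order,
    detrend_scale_s = detrend_scale_s, cwt_scale_s = cwt_scale_s,
    min_peak_separation = min_peak_separation,
    peak_prominence_frac = peak_prominence_frac,
    max_interval_s = max_interval_s
  )
  if (any(vapply(cfg, function(v) !is.numeric(v) || length(v) != 1 || v <= 0, TRUE))) {
    stop("all detector parameters must be positive scalars")
  }
  if (min_peak_separation >= max_interval_s) {
    stop("min_peak_separation must be below max_interval_s")
  }
  structure(cfg, class = "detector_config")
}

#' Detect stair-climbing initial contacts from vertical acceleration
#'
#' The core detection chain, applied to the vertical (gravity-inclusive)
#' acceleration of a stair-ascent event, in order: (1) wavelet-style
#' detrend, subtracting the coarse Gaussian-smooth component; (2)
#' zero-phase low-pass Butterworth filter; (3) cumulative
#' composite-trapezoid integration (acceleration to a velocity-like
#' signal); (4) continuous Gaussian-derivative wavelet transform; (5) peak
#' detection with prominence and separation constraints. Each detected
#' peak marks a foot's initial contact with a step.
#'
#' Peak polarity is resolved at run time by evaluating both signs of the
#' transformed signal and keeping the polarity with the larger total
#' prominence, since the sign of the vertical axis depends on mounting. If
#' more than `expected_steps` peaks survive, the `expected_steps` most
#' prominent are kept and reported in time order.
#'
#' @param x_vertical Vertical acceleration in m/s^2 (finite values).
#' @param fs Sampling rate in Hz, >= 50.
#' @param cfg A [detector_config()].
#' @param expected_steps Number of staircase steps (default 4, the
#'   four-step Stair Climb Power Test).
#' @return A `step_detection` object with `contacts` (seconds, ascending),
#'   `intervals` (`diff(contacts)`), `valid_mask` (intervals at most
#'   `cfg$max_interval_s`), plus the transformed signal for inspection.
#' @seealso [filter_step_intervals()], [stairpy_scp()]
#' @examples
#' trial <- simulate_scpt_trial(synthetic_config(seed = 7))
#' res <- detect_initial_contacts(trial$recording$accel[, "x"],
#'                                fs = trial$recording$fs)
#' res
#' @export
detect_initial_contacts <- function(x_vertical, fs, cfg = detector_config(),
                                    expected_steps = 4) {
  if (any(!is.finite(x_vertical))) stop("input error: non-finite samples in vertical acceleration")
  if (fs < 50) stop("sampling rate must be at least 50 Hz")
  n <- length(x_vertical)
  if ((n - 1) / fs < 1) stop("event too short: need at least 1 s of signal")

  detrended <- x_vertical - gaussian_smooth(x_vertical, fs, cfg$detrend_scale_s)
  bf <- signal::butter(cfg$lowpass_order, cfg$lowpass_cutoff / (fs / 2))
  filtered <- filtfilt_zi(bf$b, bf$a, detrended)
  velocity <- cumtrapz_uniform(filtered, fs)
  transformed <- cwt_gauss_deriv(velocity, fs, cfg$cwt_scale_s)

  s <- stats::sd(transformed)
  if (s == 0) {
    stop("step detection failed at peak-detection stage: transformed signal is flat")
  }
  min_sep <- max(1L, round(cfg$min_peak_separation * fs))
  min_prom <- cfg$peak_prominence_frac * s
  pos <- find_peaks(transformed, min_sep, min_prom)
  neg <- find_peaks(-transformed, min_sep, min_prom)
  peaks <- if (sum(neg$prominence) > sum(pos$prominence)) neg else pos
  if (nrow(peaks) < 2) {
    stop("step detection failed at peak-detection stage: fewer than 2 peaks found")
  }
  if (nrow(peaks) > expected_steps) {
    peaks <- peaks[order(-peaks$prominence)[seq_len(expected_steps)], , drop = FALSE]
    peaks <- peaks[order(peaks$idx), , drop = FALSE]
  }
  contacts <- (peaks$idx - 1) / fs
  res <- structure(
    list(
      contacts = contacts,
      intervals = diff(contacts),
      valid_mask = rep(TRUE, length(contacts) - 1),
      expected_steps = expected_steps,
      fs = fs,
      config = cfg,
      transformed = transformed,
      signal = x_vertical
    ),
    class = "step_detection"
  )
  filter_step_intervals(res, cfg$max_interval_s)
}

#' Flag inter-step intervals above the misdetection threshold
#'
#' Inter-step intervals longer than `max_interval_s` (default 1.2 s,
#' boundary inclusive: an interval of exactly 1.2 s is valid) correspond to
#' missed contacts on a four-step staircase and are excluded from power
#' estimation; the contacts themselves are kept.
#'
#' @param res A `step_detection` result with at least one interval.
#' @param max_interval_s Threshold in seconds (default 1.2).
#' @return `res` with an updated `valid_mask`. Warns if no interval
#'   remains valid (the trial is then unresolvable for power estimation).
#' @export
filter_step_intervals <- function(res, max_interval_s = 1.2) {
  stopifnot(inherits(res, "step_detection"), length(res$intervals) >= 1)
  res$valid_mask <- res$intervals <= max_interval_s
  if (!any(res$valid_mask)) {
    warning("no valid step intervals remain after the ", max_interval_s, " s misdetection filter")
  }
  res
}

#' @export
print.step_detection <- function(x, ...) {
  cat(sprintf("<step_detection> %d contacts (expected %d) @ %g Hz\n",
              length(x$contacts), x$expected_steps, x$fs))
  cat("  contacts (s):", paste(sprintf("%.3f", x$contacts), collapse = ", "), "\n")
  cat("  intervals (s):",
      paste(sprintf("%.3f%s", x$intervals, ifelse(x$valid_mask, "", "*")), collapse = ", "),
      if (!all(x$valid_mask)) " (* exceeds misdetection threshold)" else "", "\n")
  invisible(x)
}

#' @export
plot.step_detection <- function(x, ...) {
  t <- (seq_along(x$signal) - 1) / x$fs
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  graphics::plot(t, x$signal, type = "l", xlab = "time (s)",
                 ylab = "vertical accel (m/s²)", main = "Detected initial contacts", ...)
  graphics::abline(v = x$contacts, col = "red3", lty = 2)
  graphics::plot(t, x$transformed, type = "l", xlab = "time (s)",
                 ylab = "wavelet response")
  graphics::abline(v = x$contacts, col = "red3", lty = 2)
  invisible(x)
}
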