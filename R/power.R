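#' Stair climb power, stopwatch (Standard) formula
#'
#' The clinical Stair Climb Power Test power: the rate of doing work
#' lifting body mass through the staircase height,
#' `P = m * g * h / t` watts, with the stopwatch time `t` running from the
#' "go" command until both feet reach the top step.
#'
#' @param mass Body mass in kg (> 0).
#' @param height Staircase height climbed in meters (> 0); a four-step
#'   staircase with 0.154 m steps gives 0.616 m.
#' @param time Stopwatch time in seconds (> 0).
#' @param g Gravitational acceleration, fixed at 9.81 m/s^2.
#' @return Power in watts.
#' @examples
#' standard_scp(mass = 80, height = 0.6, time = 2.0)  # 235.44 W
#' @export
standard_scp <- function(mass, height, time, g = 9.81) {
  if (mass <= 0 || height <= 0 || time <= 0) {
    stop("mass, height and time must all be positive")
  }
  mass * g * height / time
}

#' Stair climb power from detected step intervals
#'
#' The sensor-based power estimate. With per-step height `h4` and the
#' valid inter-contact intervals, the climb time for `k` detected steps is
#' `t0 + sum(intervals)`, where `t0` — the unobserved time between "go"
#' and the first contact, during which no vertical work is done in the
#' stopwatch formula's numerator — is imputed as the mean detected step
#' interval. Algebraically this reduces to
#' `P = m * g * h4 / mean(valid intervals)`, which is the form computed
#' here; it coincides exactly with the explicit `t0`-plus-telescoping-sum
#' expression when all intervals are valid, and extends it to partial
#' detections (missed contacts) by simply dropping intervals flagged by
#' the misdetection filter.
#'
#' @param mass Body mass in kg.
#' @param intervals Inter-contact intervals in seconds, or a
#'   `step_detection` object (its intervals and validity mask are used).
#' @param valid_mask Logical vector marking usable intervals; defaults to
#'   all valid (ignored when `intervals` is a `step_detection`).
#' @param step_height Per-step height in meters (default 0.154).
#' @param g Gravitational acceleration, 9.81 m/s^2.
#' @return An `scp_result`: power in watts plus the components
#'   (mass, g, step height, intervals, `t0`) that produced it and a
#'   calibration offset (0 until [apply_calibration()] is used).
#' @examples
#' r <- stairpy_scp(70, intervals = c(0.64, 0.64, 0.64))
#' r$power  # 165.2372 W
#' @export
stairpy_scp <- function(mass, intervals, valid_mask = NULL, step_height = 0.154,
                        g = 9.81) {
  if (inherits(intervals, "step_detection")) {
    valid_mask <- intervals$valid_mask
    intervals <- intervals$intervals
  }
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, length(intervals))
  stopifnot(length(valid_mask) == length(intervals))
  if (mass <= 0 || step_height <= 0 || any(intervals <= 0)) {
    stop("mass, step_height and intervals must all be positive")
  }
  valid <- intervals[valid_mask]
  if (!length(valid)) {
    stop("unresolvable trial: no valid step intervals for power estimation")
  }
  t0 <- mean(valid)
  structure(
    list(
      power = mass * g * step_height / t0,
      method = "stairpy",
      components = list(mass = mass, g = g, step_height = step_height,
                        intervals = intervals, valid_mask = valid_mask,
                        n_valid = length(valid), t0 = t0),
      calibration_offset = 0
    ),
    class = "scp_result"
  )
}

#' Apply an additive calibration offset to a power estimate
#'
#' An optional post-hoc adjustment for systematic bias between the
#' sensor-based and stopwatch methods. Off (0 W) by default: the `t0`
#' imputation inside [stairpy_scp()] already accounts for the pre-first-step
#' period, and the uncalibrated estimate is the primary output. Offsets
#' compose additively and are recorded in the result.
#'
#' @param res An `scp_result`.
#' @param offset Watts to add (may be negative).
#' @return The adjusted `scp_result`.
#' @export
apply_calibration <- function(res, offset) {
  stopifnot(inherits(res, "scp_result"), is.numeric(offset), length(offset) == 1)
  res$power <- res$power + offset
  res$calibration_offset <- res$calibration_offset + offset
  res
}

#' @export
print.scp_result <- function(x, ...) {
  cat(sprintf("<scp_result> %.2f W (%s)\n", x$power, x$method))
  cmp <- x$components
  cat(sprintf("  mass %.1f kg, step height %.3f m, t0 %.3f s, %d valid interval(s)\n",
              cmp$mass, cmp$step_height, cmp$t0, cmp$n_valid))
  if (x$calibration_offset != 0) {
    cat(sprintf("  calibration offset %+.2f W applied\n", x$calibration_offset))
  }
  invisible(x)
}
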