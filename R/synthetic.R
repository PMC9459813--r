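#' Configuration for the synthetic lumbar-IMU generator
#'
#' The generator emulates the in-clinic protocol the pipeline targets:
#' four-step Stair Climb Power Test trials (a burst of `n_steps` vertical
#' foot-contact impacts over roughly 2-4 s at a natural pace), stair
#' descent with sharper, narrower impacts and opposite trunk-pitch bias,
#' and level gait with sustained 1.5-2.2 Hz periodicity and lower vertical
#' transient energy.
#'
#' Each foot contact contributes a Gaussian transient (net vertical
#' impulse) plus a Gaussian-enveloped 8 Hz ring (heel-strike vibration) to
#' the gravity-inclusive vertical axis; anterior-posterior and
#' medial-lateral accelerations and the pitch gyroscope carry
#' class-appropriate oscillations. Noise is low-pass filtered (coloured)
#' white noise. `class_contrast` scales every class-distinguishing
#' component: at 0 all three activities reduce to the same gait-like
#' process (a null generator for permutation-style checks).
#'
#' @param fs Sampling rate in Hz (default 128, the study-device rate).
#' @param n_steps Staircase steps per trial (default 4).
#' @param step_time_range Uniform range of inter-contact intervals in
#'   seconds (default `c(0.4, 1.0)`, natural-pace stair climbing).
#' @param impact_amplitude Named m/s^2 amplitudes for ascent and descent
#'   contact transients.
#' @param impact_width_s Named Gaussian widths (sd, seconds) of the
#'   contact transients; descent impacts are sharper.
#' @param ring_frac,ring_freq_hz Relative amplitude and frequency of the
#'   heel-strike ring superimposed on each impact.
#' @param gait_freq_range Step-frequency range for level gait, Hz.
#' @param gait_amplitude Vertical gait oscillation amplitude, m/s^2.
#' @param pitch_amplitude Trunk-pitch gyroscope amplitude, rad/s (positive
#'   bias during ascent, negative during descent).
#' @param noise_sd_accel,noise_sd_gyro Noise standard deviations (m/s^2,
#'   rad/s).
#' @param lead_in_s,lead_out_s Quiet signal before the first and after the
#'   last contact, seconds.
#' @param class_contrast Scale of class-distinguishing structure in
#'   `[0, 1]`.
#' @param seed Integer seed fixing the full output; `NULL` leaves the RNG
#'   stream untouched.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(fs = 128, n_steps = 4,
                             step_time_range = c(0.4, 1.0),
                             impact_amplitude = c(ascent = 3.0, descent = 3.5),
                             impact_width_s = c(ascent = 0.05, descent = 0.03),
                             ring_frac = 0.5, ring_freq_hz = 8,
                             gait_freq_range = c(1.5, 2.2),
                             gait_amplitude = 1.5,
                             pitch_amplitude = 0.3,
                             noise_sd_accel = 0.3, noise_sd_gyro = 0.05,
                             lead_in_s = 1.0, lead_out_s = 1.0,
                             class_contrast = 1, seed = NULL) {
  stopifnot(fs > 0, n_steps >= 2, step_time_range[1] < step_time_range[2],
            all(step_time_range > 0), all(impact_amplitude > 0),
            all(impact_width_s > 0), gait_freq_range[1] < gait_freq_range[2],
            noise_sd_accel >= 0, noise_sd_gyro >= 0,
            class_contrast >= 0, class_contrast <= 1)
  structure(
    list(fs = fs, n_steps = n_steps, step_time_range = step_time_range,
         impact_amplitude = impact_amplitude, impact_width_s = impact_width_s,
         ring_frac = ring_frac, ring_freq_hz = ring_freq_hz,
         gait_freq_range = gait_freq_range, gait_amplitude = gait_amplitude,
         pitch_amplitude = pitch_amplitude,
         noise_sd_accel = noise_sd_accel, noise_sd_gyro = noise_sd_gyro,
         lead_in_s = lead_in_s, lead_out_s = lead_out_s,
         class_contrast = class_contrast, seed = seed),
    class = "synthetic_config"
  )
}

coloured_noise <- function(n, fs, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  e <- stats::rnorm(n)
  bf <- signal::butter(2, min(0.9, 12 / (fs / 2)))
  e <- filtfilt_zi(bf$b, bf$a, e)
  e / stats::sd(e) * sd_target
}

# six-channel signal content for one activity bout on a given time grid;
# contacts may be NULL (gait). phi0 is a per-recording phase offset of the
# locomotor oscillation (a recording never starts at a fixed gait phase).
activity_channels <- function(t, cfg, label, contacts, amp_mult = 1,
                              gait_freq = NULL, phi0 = 0) {
  cc <- cfg$class_contrast
  if (is.null(gait_freq)) gait_freq <- mean(cfg$gait_freq_range)
  n <- length(t)
  base_osc <- cfg$gait_amplitude * amp_mult * sin(2 * pi * gait_freq * t + phi0)
  ax <- rep(9.81, n)
  gy <- numeric(n)
  gait_ax <- base_osc +
    0.3 * cfg$gait_amplitude * amp_mult * sin(4 * pi * gait_freq * t + 2 * phi0 + 0.7)
  if (label == "gait") {
    ax <- ax + gait_ax
  } else {
    # stair classes: a step-cycle oscillation phase-locked to the contacts
    # (trunk vertical acceleration peaks at each foot strike), confined to
    # the stepping burst, plus the contact transients. The class-specific
    # content is blended against the plain gait process by class_contrast,
    # so at contrast 0 every activity reduces to the same process.
    mean_iv <- if (length(contacts) > 1) mean(diff(contacts)) else 1 / gait_freq
    phase <- stats::approx(contacts, seq_along(contacts), xout = t, rule = 2)$y +
      pmin(0, (t - min(contacts)) / mean_iv) + pmax(0, (t - max(contacts)) / mean_iv)
    # smooth onset/offset so the bout does not start with a hard edge
    burst <- pmin(1, pmax(0, (t - min(contacts) + 0.5) / 0.3)) *
      pmin(1, pmax(0, (max(contacts) + 0.5 - t) / 0.3))
    stair_ax <- cfg$gait_amplitude * amp_mult * cos(2 * pi * phase) * burst
    A <- cfg$impact_amplitude[[label]] * amp_mult
    w <- cfg$impact_width_s[[label]]
    for (tc in contacts) {
      env <- exp(-(t - tc)^2 / (2 * w^2))
      stair_ax <- stair_ax +
        A * env * (1 + cfg$ring_frac * cos(2 * pi * cfg$ring_freq_hz * (t - tc)))
    }
    ax <- ax + (1 - cc) * gait_ax + cc * stair_ax
    sgn <- if (label == "ascent") 1 else -1
    gy <- gy + sgn * cc * cfg$pitch_amplitude * amp_mult * burst *
      (0.6 + 0.4 * sin(2 * pi * gait_freq * t + phi0))
  }
  az <- 0.8 * cfg$gait_amplitude * amp_mult * sin(2 * pi * gait_freq * t + phi0 + pi / 3)
  ay <- 0.5 * cfg$gait_amplitude * amp_mult * sin(pi * gait_freq * t + phi0 / 2 + 1.1)
  gy <- gy + 0.15 * amp_mult * sin(2 * pi * gait_freq * t + phi0 + 0.4)
  gx <- 0.08 * amp_mult * sin(pi * gait_freq * t + phi0 / 2 + 2.0)
  gz <- 0.08 * amp_mult * sin(2 * pi * gait_freq * t + phi0 + 0.9)
  list(ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz)
}

#' Simulate one Stair Climb Power Test trial
#'
#' Generates a six-axis lumbar recording of a single stair bout (default:
#' ascent) with known ground truth: the drawn contact times and the true
#' stair climb power `m * g * h4 / mean(true intervals)`.
#'
#' @param cfg A [synthetic_config()]; `cfg$seed` (if non-`NULL`) makes the
#'   trial fully reproducible.
#' @param mass Body mass in kg used for the true power.
#' @param label `"ascent"` or `"descent"`.
#' @param step_times Optional fixed contact times in seconds (overrides
#'   the random draw); the first contact otherwise falls at
#'   `cfg$lead_in_s`.
#' @param step_height Per-step height in meters for the true power.
#' @param drop_contacts Optional indices of contacts whose impacts are
#'   omitted from the signal (the truth keeps them), emulating a missed
#'   step for misdetection studies.
#' @param gait_freq Frequency of the underlying locomotor oscillation in
#'   Hz; defaults to the stepping rate `1 / mean(step interval)`.
#' @param amp_mult Subject-level signal amplitude multiplier.
#' @return A `synthetic_trial`: `recording` ([imu_recording()]),
#'   `truth_contacts`, `label`, `mass`, `true_scp`.
#' @examples
#' trial <- simulate_scpt_trial(synthetic_config(seed = 7), mass = 70)
#' trial$true_scp
#' @export
simulate_scpt_trial <- function(cfg = synthetic_config(), mass = 70,
                                label = c("ascent", "descent"),
                                step_times = NULL, step_height = 0.154,
                                drop_contacts = integer(0), gait_freq = NULL,
                                amp_mult = 1) {
  label <- match.arg(label)
  stopifnot(inherits(cfg, "synthetic_config"), mass > 0)
  with_seed(cfg$seed, {
    if (is.null(step_times)) {
      iv <- stats::runif(cfg$n_steps - 1, cfg$step_time_range[1], cfg$step_time_range[2])
      contacts <- cfg$lead_in_s + c(0, cumsum(iv))
    } else {
      stopifnot(length(step_times) == cfg$n_steps, !is.unsorted(step_times))
      contacts <- step_times
    }
    dur <- max(contacts) + cfg$lead_out_s
    t <- seq(0, dur, by = 1 / cfg$fs)
    signal_contacts <- if (length(drop_contacts)) contacts[-drop_contacts] else contacts
    phi0 <- stats::runif(1, 0, 2 * pi)
    ch <- activity_channels(t, cfg, label, signal_contacts, amp_mult = amp_mult,
                            gait_freq = if (is.null(gait_freq)) 1 / mean(diff(contacts)) else gait_freq,
                            phi0 = phi0)
    na <- cfg$noise_sd_accel
    ng <- cfg$noise_sd_gyro
    accel <- cbind(x = ch$ax + coloured_noise(length(t), cfg$fs, na),
                   y = ch$ay + coloured_noise(length(t), cfg$fs, 0.7 * na),
                   z = ch$az + coloured_noise(length(t), cfg$fs, 0.7 * na))
    gyro <- cbind(x = ch$gx + coloured_noise(length(t), cfg$fs, ng),
                  y = ch$gy + coloured_noise(length(t), cfg$fs, ng),
                  z = ch$gz + coloured_noise(length(t), cfg$fs, ng))
    rec <- imu_recording(accel = accel, fs = cfg$fs, gyro = gyro)
    structure(
      list(recording = rec, truth_contacts = contacts, label = label, mass = mass,
           true_scp = if (label == "ascent") {
             mass * 9.81 * step_height / mean(diff(contacts))
           } else NA_real_),
      class = "synthetic_trial"
    )
  })
}

#' Simulate a level-gait recording
#'
#' @param cfg A [synthetic_config()].
#' @param duration_s Recording length in seconds.
#' @param gait_freq Step frequency in Hz; drawn from
#'   `cfg$gait_freq_range` when `NULL`.
#' @param amp_mult Subject-level amplitude multiplier.
#' @return An [imu_recording()].
#' @export
simulate_gait_recording <- function(cfg = synthetic_config(), duration_s = 15,
                                    gait_freq = NULL, amp_mult = 1) {
  stopifnot(inherits(cfg, "synthetic_config"), duration_s > 0)
  with_seed(cfg$seed, {
    if (is.null(gait_freq)) {
      gait_freq <- stats::runif(1, cfg$gait_freq_range[1], cfg$gait_freq_range[2])
    }
    t <- seq(0, duration_s, by = 1 / cfg$fs)
    ch <- activity_channels(t, cfg, "gait", NULL, amp_mult = amp_mult,
                            gait_freq = gait_freq, phi0 = stats::runif(1, 0, 2 * pi))
    na <- cfg$noise_sd_accel
    ng <- cfg$noise_sd_gyro
    accel <- cbind(x = ch$ax + coloured_noise(length(t), cfg$fs, na),
                   y = ch$ay + coloured_noise(length(t), cfg$fs, 0.7 * na),
                   z = ch$az + coloured_noise(length(t), cfg$fs, 0.7 * na))
    gyro <- cbind(x = ch$gx + coloured_noise(length(t), cfg$fs, ng),
                  y = ch$gy + coloured_noise(length(t), cfg$fs, ng),
                  z = ch$gz + coloured_noise(length(t), cfg$fs, ng))
    imu_recording(accel = accel, fs = cfg$fs, gyro = gyro)
  })
}

#' Simulate a labeled multi-subject window dataset
#'
#' Draws subject-level random effects (preferred step interval, signal
#' amplitude, gait frequency), generates ascent, descent and gait
#' recordings per subject, visit and trial, resamples them to
#' `window_fs`, and windows them with [make_windows()] so balancing and
#' grouped cross-validation can be exercised end to end. Subject-level
#' effects make pooled and subject-grouped cross-validation differ
#' measurably, so fold-leakage bugs are detectable.
#'
#' @param cfg A [synthetic_config()]; `cfg$seed` fixes the whole dataset.
#' @param n_subjects Number of subjects (>= 2).
#' @param trials_per_subject Stair trials per subject and visit.
#' @param n_visits Visits per subject.
#' @param gait_duration_s Gait recording length per visit, seconds. The
#'   default (30 s, a structured walking bout several times longer than a
#'   single four-step stair trial, as in clinic protocols) guarantees at
#'   least as many gait windows per visit as stair windows, so per-visit
#'   class balancing never starves.
#' @param window_fs Windowing rate in Hz (default 50).
#' @return A list with `windows` (list of `segment_window`) and `trials`
#'   (a `data.frame` of per-trial ground truth: subject, visit, trial,
#'   mass, true ascent SCP).
#' @export
simulate_labeled_dataset <- function(cfg = synthetic_config(), n_subjects = 10,
                                     trials_per_subject = 2, n_visits = 1,
                                     gait_duration_s = 30, window_fs = 50) {
  stopifnot(n_subjects >= 2)
  with_seed(cfg$seed, {
    windows <- list()
    truth <- list()
    for (s in seq_len(n_subjects)) {
      sid <- sprintf("S%02d", s)
      mass <- stats::runif(1, 55, 95)
      amp_mult <- stats::runif(1, 0.8, 1.25)
      subj_step <- stats::runif(1, cfg$step_time_range[1] + 0.05, cfg$step_time_range[2] - 0.05)
      subj_gait_freq <- stats::runif(1, cfg$gait_freq_range[1], cfg$gait_freq_range[2])
      for (v in seq_len(n_visits)) {
        vid <- sprintf("V%d", v)
        sub_cfg <- cfg
        sub_cfg$seed <- NULL  # inherit the surrounding stream
        for (tr in seq_len(trials_per_subject)) {
          for (lab in c("ascent", "descent")) {
            iv <- subj_step + stats::runif(cfg$n_steps - 1, -0.05, 0.05)
            st <- cfg$lead_in_s + c(0, cumsum(iv))
            trial <- simulate_scpt_trial(sub_cfg, mass = mass, label = lab,
                                         step_times = st, gait_freq = subj_gait_freq,
                                         amp_mult = amp_mult)
            rec <- resample_recording(trial$recording, window_fs)
            rec$subject_id <- sid
            rec$visit_id <- vid
            windows <- c(windows, make_windows(rec, lab, task_id = sprintf("%s_T%d", lab, tr)))
            if (lab == "ascent") {
              truth[[length(truth) + 1]] <- data.frame(
                subject_id = sid, visit_id = vid, trial = tr, mass = mass,
                true_scp = trial$true_scp
              )
            }
          }
        }
        grec <- simulate_gait_recording(sub_cfg, duration_s = gait_duration_s,
                                        gait_freq = subj_gait_freq, amp_mult = amp_mult)
        grec <- resample_recording(grec, window_fs)
        grec$subject_id <- sid
        grec$visit_id <- vid
        windows <- c(windows, make_windows(grec, "gait", task_id = "gait_T1"))
      }
    }
    list(windows = windows, trials = do.call(rbind, truth))
  })
}
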