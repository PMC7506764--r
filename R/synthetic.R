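# Seeded synthetic wrist-IMU trial generator with known ground-truth
# repetition counts. Each exercise class is modelled as a periodic limb
# movement with one dominant sensor channel (the sensor/axis mapping of the
# ten rehabilitation exercises), harmonics shaping the waveform, cross-coupled
# secondary channels, a gravity offset on the accelerometer, and additive
# Gaussian sensor noise. The "others" class is an aperiodic transient train.

channel_range <- function(channel) {
  ifelse(grepl("^acc", channel), ACC_RANGE_G, GYRO_RANGE_DPS)
}

dominant_channel_name <- function(sensor, axis) {
  paste0(ifelse(sensor == "accelerometer", "acc", "gyro"), "_", tolower(axis))
}

#' Construct a generative profile for one exercise class
#'
#' @param label class label, one of [exercise_labels()].
#' @param dominant_sensor `"accelerometer"` or `"gyroscope"`.
#' @param dominant_axis `"X"`, `"Y"` or `"Z"`.
#' @param period_s repetition period in seconds (default 4, the nominal
#'   duration of one repetition).
#' @param amplitude dominant-axis peak amplitude in the sensor's natural units
#'   (g for accelerometer, deg/s for gyroscope).
#' @param harmonics relative amplitudes of harmonics 2, 3, ... of the base
#'   sinusoid (the fundamental has relative amplitude 1). Kept small so each
#'   period has exactly one maximum and one minimum.
#' @param harmonic_phase phase offsets (radians) of the harmonics; nonzero
#'   offsets make the waveform asymmetric (unequal positive/negative
#'   excursions), so the global extremum of a window is unambiguous; the
#'   default places the larger excursion early in the cycle (fast concentric,
#'   slower eccentric movement). Default
#'   `-pi/2` for every harmonic.
#' @param cross_coupling named fractions in `[0, 0.6)` of the (range-scaled)
#'   dominant amplitude leaked into each of the five secondary channels.
#' @param coupling_phase named phase offsets (radians) of the secondary
#'   channels relative to the dominant waveform.
#' @param gravity 3-vector of the constant gravity projection on the
#'   accelerometer axes, in g (norm approximately 1).
#' @param noise_sd additive Gaussian noise level, as a fraction of the
#'   range-scaled dominant amplitude (applied to every channel in its own
#'   units).
#' @param jitter named vector `c(period = ..., amplitude = ...)`: fractional
#'   per-repetition variability applied in unconstrained mode (both in
#'   `[0, 0.5]`).
#' @param aperiodic flag for the "others" profile (no sustained periodicity).
#' @return an object of class `exercise_profile`.
#' @export
exercise_profile <- function(label, dominant_sensor, dominant_axis,
                             period_s = 4.0, amplitude,
                             harmonics = c(0.1),
                             harmonic_phase = NULL,
                             cross_coupling = NULL,
                             coupling_phase = NULL,
                             gravity = c(0.1, 0.05, 0.99),
                             noise_sd = 0.05,
                             jitter = c(period = 0.10, amplitude = 0.15),
                             aperiodic = FALSE) {
  stopifnot(label %in% exercise_labels())
  stopifnot(dominant_sensor %in% c("accelerometer", "gyroscope"))
  stopifnot(dominant_axis %in% c("X", "Y", "Z"))
  if (period_s <= 0) stop("period_s must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(jitter < 0) || any(jitter > 0.5)) stop("jitter must lie in [0, 0.5]")
  dom <- dominant_channel_name(dominant_sensor, dominant_axis)
  secondary <- setdiff(CHANNELS, dom)
  if (is.null(cross_coupling)) {
    cross_coupling <- stats::setNames(rep(0.2, 5), secondary)
  }
  if (is.null(coupling_phase)) {
    coupling_phase <- stats::setNames(seq(0.4, 2.0, length.out = 5), secondary)
  }
  cross_coupling <- cross_coupling[secondary]
  coupling_phase <- coupling_phase[secondary]
  if (any(is.na(cross_coupling)) || any(cross_coupling < 0) ||
      any(cross_coupling >= 0.6)) {
    stop("cross_coupling fractions must be named for all secondary channels and lie in [0, 0.6)")
  }
  baseline <- if (dominant_sensor == "accelerometer") {
    gravity[match(tolower(dominant_axis), c("x", "y", "z"))]
  } else 0
  harmonic_phase <- harmonic_phase %||% rep(-pi / 2, length(harmonics))
  stopifnot(length(harmonic_phase) == length(harmonics))
  structure(
    list(label = label, dominant_sensor = dominant_sensor,
         dominant_axis = dominant_axis, dominant_channel = dom,
         period_s = period_s, amplitude = amplitude, baseline = baseline,
         harmonics = harmonics, harmonic_phase = harmonic_phase,
         cross_coupling = cross_coupling,
         coupling_phase = coupling_phase, gravity = gravity,
         noise_sd = noise_sd, jitter = jitter, aperiodic = aperiodic),
    class = "exercise_profile"
  )
}

#' Default generative profiles for the 11 classes
#'
#' The (sensor, axis) pair of each of the ten exercises follows the dominant-
#' axis mapping observed for a right-wrist-worn sensor: BC/FR/LR/TER/SQ/L are
#' accelerometer-X dominant, LLR accelerometer-Y, PD/SBC gyroscope-X and TT
#' gyroscope-Y. Amplitudes, harmonic mixes, cross-coupling patterns and wrist
#' orientations (gravity projections) differ per class so that classes sharing
#' a dominant axis remain statistically separable. The OTH profile is flagged
#' aperiodic and handled by [simulate_others()].
#'
#' @return named list of 11 `exercise_profile` objects.
#' @export
default_profiles <- function() {
  cc <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), names(v))
  }
  p <- list(
    BC = exercise_profile("BC", "accelerometer", "X",
      amplitude = 1.10, harmonics = c(0.20, 0.05),
      cross_coupling = cc(acc_y = 0.30, acc_z = 0.20, gyro_x = 0.25,
                          gyro_y = 0.10, gyro_z = 0.05),
      gravity = c(0.20, 0.10, 0.97)),
    FR = exercise_profile("FR", "accelerometer", "X",
      amplitude = 0.80, harmonics = c(0.05, 0.12),
      cross_coupling = cc(acc_y = 0.15, acc_z = 0.35, gyro_x = 0.10,
                          gyro_y = 0.30, gyro_z = 0.08),
      gravity = c(-0.10, 0.15, 0.98)),
    LR = exercise_profile("LR", "accelerometer", "X",
      amplitude = 0.60, harmonics = c(0.22),
      cross_coupling = cc(acc_y = 0.40, acc_z = 0.10, gyro_x = 0.08,
                          gyro_y = 0.12, gyro_z = 0.30),
      gravity = c(0.05, -0.20, 0.97)),
    TER = exercise_profile("TER", "accelerometer", "X",
      amplitude = 0.45, harmonics = c(0.10, 0.10),
      cross_coupling = cc(acc_y = 0.10, acc_z = 0.15, gyro_x = 0.35,
                          gyro_y = 0.05, gyro_z = 0.20),
      gravity = c(0.30, 0.05, 0.95)),
    PD = exercise_profile("PD", "gyroscope", "X",
      amplitude = 120, harmonics = c(0.15),
      cross_coupling = cc(acc_x = 0.30, acc_y = 0.20, acc_z = 0.10,
                          gyro_y = 0.25, gyro_z = 0.15),
      gravity = c(0.10, 0.25, 0.96)),
    TT = exercise_profile("TT", "gyroscope", "Y",
      amplitude = 150, harmonics = c(0.10, 0.05),
      cross_coupling = cc(acc_x = 0.15, acc_y = 0.30, acc_z = 0.05,
                          gyro_x = 0.20, gyro_z = 0.35),
      gravity = c(-0.05, 0.10, 0.99)),
    SBC = exercise_profile("SBC", "gyroscope", "X",
      amplitude = 200, harmonics = c(0.22),
      cross_coupling = cc(acc_x = 0.20, acc_y = 0.10, acc_z = 0.30,
                          gyro_y = 0.35, gyro_z = 0.10),
      gravity = c(0.15, -0.10, 0.98)),
    SQ = exercise_profile("SQ", "accelerometer", "X",
      amplitude = 0.35, harmonics = c(0.15, 0.10),
      cross_coupling = cc(acc_y = 0.25, acc_z = 0.40, gyro_x = 0.12,
                          gyro_y = 0.08, gyro_z = 0.10),
      gravity = c(0.02, 0.30, 0.95)),
    LLR = exercise_profile("LLR", "accelerometer", "Y",
      amplitude = 0.70, harmonics = c(0.12),
      cross_coupling = cc(acc_x = 0.35, acc_z = 0.20, gyro_x = 0.10,
                          gyro_y = 0.20, gyro_z = 0.25),
      gravity = c(0.25, 0.15, 0.96)),
    L = exercise_profile("L", "accelerometer", "X",
      amplitude = 0.90, harmonics = c(0.08, 0.15),
      cross_coupling = cc(acc_y = 0.20, acc_z = 0.25, gyro_x = 0.30,
                          gyro_y = 0.15, gyro_z = 0.12),
      gravity = c(-0.20, 0.05, 0.97)),
    OTH = exercise_profile("OTH", "accelerometer", "Z",
      amplitude = 0.8, harmonics = c(0.1), aperiodic = TRUE,
      gravity = c(0.10, 0.05, 0.99))
  )
  p
}

# Periodic waveform: fundamental sine plus small phase-shifted higher
# harmonics. A sum of pure sine harmonics is antisymmetric about the
# half-period (equal positive and negative excursions), so each harmonic
# carries a phase offset to make the waveform genuinely asymmetric — one
# excursion strictly larger than the other, as in real limb movement. The
# constant correction keeps the waveform exactly zero at integer phase, so
# per-repetition amplitude steps stay continuous.
profile_wave <- function(phase, harmonics, phases = NULL) {
  phases <- phases %||% rep(-pi / 2, length(harmonics))
  w <- sin(2 * pi * phase)
  for (k in seq_along(harmonics)) {
    w <- w + harmonics[k] *
      (sin(2 * pi * (k + 1) * phase + phases[k]) - sin(phases[k]))
  }
  w
}

random_rotation <- function(max_angle_deg) {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 2, max_angle_deg) * pi / 180
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * k + (1 - cos(ang)) * (k %*% k)
}

#' Simulate one exercise trial with known ground truth
#'
#' Generates `n_reps` repetitions of the profile's periodic waveform at
#' sampling rate `fs`. In `"constrained"` mode every repetition has the same
#' period and amplitude; `"unconstrained"` mode applies per-repetition period
#' and amplitude jitter plus a small fixed 3D rotation of the sensor frame
#' (emulating a different plane of limb movement and rest position). Identical
#' arguments and seed give identical output.
#'
#' @param profile an [exercise_profile()].
#' @param n_reps number of repetitions (>= 0; at 0 the recording is baseline
#'   plus noise only, one second long).
#' @param fs sampling rate in Hz (>= 32).
#' @param mode `"constrained"` or `"unconstrained"`.
#' @param seed integer seed.
#' @param subject_id subject identifier stored in the recording.
#' @return list with `recording` (an `imu_recording`) and `truth` (a
#'   `ground_truth`: `n_reps`, `peak_times`, `valley_times` in seconds).
#' @export
simulate_exercise <- function(profile, n_reps, fs = 512,
                              mode = c("constrained", "unconstrained"),
                              seed = 1, subject_id = "S001") {
  mode <- match.arg(mode)
  if (!is_count(n_reps)) stop("argument error: n_reps must be a non-negative integer")
  if (!is.numeric(fs) || fs < 32) stop("argument error: fs must be >= 32 Hz")
  if (profile$aperiodic) {
    stop("aperiodic profile: use simulate_others() for the OTH class")
  }
  with_seed(seed, {
    jp <- if (mode == "unconstrained") profile$jitter[["period"]] else 0
    ja <- if (mode == "unconstrained") profile$jitter[["amplitude"]] else 0
    as_scaled <- profile$amplitude / channel_range(profile$dominant_channel)
    if (n_reps == 0) {
      n <- round(fs)
      tt <- (0:(n - 1)) / fs
      clean <- matrix(0, n, 6, dimnames = list(NULL, CHANNELS))
      rep_of <- integer(0)
      periods <- numeric(0)
      bounds <- 0
    } else {
      periods <- profile$period_s * (1 + jp * stats::runif(n_reps, -1, 1))
      ampf <- 1 + ja * stats::runif(n_reps, -1, 1)
      bounds <- c(0, cumsum(periods))
      n <- floor(sum(periods) * fs)
      tt <- (0:(n - 1)) / fs
      rep_of <- pmin(pmax(findInterval(tt, bounds), 1L), n_reps)
      phase <- (rep_of - 1) + (tt - bounds[rep_of]) / periods[rep_of]
      af <- ampf[rep_of]
      clean <- matrix(0, n, 6, dimnames = list(NULL, CHANNELS))
      clean[, profile$dominant_channel] <-
        profile$amplitude * af *
        profile_wave(phase, profile$harmonics, profile$harmonic_phase)
      for (ch in names(profile$cross_coupling)) {
        amp_c <- profile$cross_coupling[[ch]] * as_scaled * channel_range(ch)
        clean[, ch] <- amp_c * af *
          sin(2 * pi * phase + profile$coupling_phase[[ch]])
      }
    }
    # ground truth from the noiseless dominant channel, per repetition
    if (n_reps > 0) {
      dom_clean <- clean[, profile$dominant_channel]
      peak_times <- valley_times <- numeric(n_reps)
      for (i in seq_len(n_reps)) {
        idx <- which(rep_of == i)
        peak_times[i] <- tt[idx[which.max(dom_clean[idx])]]
        valley_times[i] <- tt[idx[which.min(dom_clean[idx])]]
      }
    } else {
      peak_times <- valley_times <- numeric(0)
    }
    clean[, 1:3] <- sweep(clean[, 1:3, drop = FALSE], 2, profile$gravity, "+")
    if (mode == "unconstrained") {
      r3 <- random_rotation(10)
      clean[, 1:3] <- clean[, 1:3] %*% t(r3)
      clean[, 4:6] <- clean[, 4:6] %*% t(r3)
    }
    noisy <- clean
    for (j in seq_along(CHANNELS)) {
      sd_j <- profile$noise_sd * as_scaled * channel_range(CHANNELS[j])
      if (sd_j > 0) noisy[, j] <- noisy[, j] + stats::rnorm(n, sd = sd_j)
    }
    noisy[, 1:3] <- pmin(pmax(noisy[, 1:3], -ACC_RANGE_G), ACC_RANGE_G)
    noisy[, 4:6] <- pmin(pmax(noisy[, 4:6], -GYRO_RANGE_DPS), GYRO_RANGE_DPS)
    rec <- imu_recording(subject_id, profile$label, mode, fs, tt,
                         noisy[, 1:3], noisy[, 4:6])
    truth <- structure(
      list(n_reps = as.integer(n_reps), peak_times = peak_times,
           valley_times = valley_times),
      class = "ground_truth"
    )
    list(recording = rec, truth = truth)
  })
}

#' Simulate an aperiodic "others" trial
#'
#' Non-exercise movement (side bending, sit-to-stand, arm stretching and the
#' like) is emulated as a train of smooth half-cosine transients with random
#' durations, amplitudes, channels and inter-transient gaps, on top of a
#' gravity offset and sensor noise. The random gaps destroy any sustained
#' periodicity.
#'
#' @param duration_s recording length in seconds (> 0; default 30).
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param subject_id subject identifier.
#' @param session session tag stored in the recording.
#' @return an `imu_recording` with label `"OTH"`.
#' @export
simulate_others <- function(duration_s = 30, fs = 512, seed = 1,
                            subject_id = "S001", session = "unconstrained") {
  if (duration_s <= 0) stop("argument error: duration_s must be > 0")
  with_seed(seed, {
    n <- floor(duration_s * fs)
    tt <- (0:(n - 1)) / fs
    x <- matrix(0, n, 6, dimnames = list(NULL, CHANNELS))
    cursor <- stats::runif(1, 0, 1.0)
    while (cursor < duration_s) {
      dur <- stats::runif(1, 0.4, 2.0)
      ch <- sample(6, 1)
      amp <- if (ch <= 3) stats::runif(1, 0.3, 1.0) else stats::runif(1, 40, 150)
      sgn <- sample(c(-1, 1), 1)
      idx <- which(tt >= cursor & tt < cursor + dur)
      if (length(idx) > 1) {
        bump <- sgn * amp * (1 - cos(2 * pi * (tt[idx] - cursor) / dur)) / 2
        x[idx, ch] <- x[idx, ch] + bump
        ch2 <- sample(setdiff(1:6, ch), 1)
        scale2 <- if (ch2 <= 3) 1 / channel_range(CHANNELS[ch]) *
          channel_range(CHANNELS[ch2]) else
          channel_range(CHANNELS[ch2]) / channel_range(CHANNELS[ch])
        x[idx, ch2] <- x[idx, ch2] + 0.3 * bump * scale2
      }
      cursor <- cursor + dur + stats::runif(1, 0.3, 2.5)
    }
    gravity <- c(0.10, 0.05, 0.99)
    x[, 1:3] <- sweep(x[, 1:3, drop = FALSE], 2, gravity, "+")
    noise_sd <- c(rep(0.02, 3), rep(2.5, 3))  # g / deg per s
    for (j in 1:6) {
      x[, j] <- x[, j] + stats::rnorm(n, sd = noise_sd[j])
    }
    x[, 1:3] <- pmin(pmax(x[, 1:3], -ACC_RANGE_G), ACC_RANGE_G)
    x[, 4:6] <- pmin(pmax(x[, 4:6], -GYRO_RANGE_DPS), GYRO_RANGE_DPS)
    imu_recording(subject_id, "OTH", session, fs, tt, x[, 1:3], x[, 4:6])
  })
}

default_dataset_config <- function() {
  list(
    root = NULL,
    splits = list(train = list(subjects = 2),
                  validation = list(subjects = 1),
                  test = list(subjects = 1)),
    labels = exercise_labels(),
    trials_per_class = 1,
    fs = 64,
    n_reps = c(6, 8),
    sessions = c("constrained", "unconstrained")
  )
}

#' Generate a class-folder dataset tree of synthetic trials
#'
#' Emits the layout `<root>/<split>/<LABEL>/<subject>_<session>_<k>.csv` with
#' subjects disjoint across splits, plus a `manifest.csv` at the root holding
#' the ground-truth repetition count and per-trial seed of every file.
#' Regeneration with the same config and seed is byte-identical.
#'
#' @param config named list (or path to a YAML file): `root` (output
#'   directory, required), `splits` (named list, each with `subjects`),
#'   `labels`, `trials_per_class` (per subject), `fs`, `n_reps` (range
#'   `c(lo, hi)` sampled per trial), `sessions` (cycled over trials).
#'   Unknown keys are a config error.
#' @param seed integer master seed; per-trial seeds are derived from it.
#' @return the manifest as a data.frame, invisibly.
#' @export
make_dataset <- function(config, seed = 1) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- default_dataset_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$root)) stop("config error: 'root' is required")
  if (!all(cfg$labels %in% exercise_labels())) {
    stop("config error: unknown label(s) in 'labels'")
  }
  if (length(cfg$n_reps) == 1) cfg$n_reps <- rep(cfg$n_reps, 2)
  profiles <- default_profiles()
  split_names <- names(cfg$splits)
  n_subjects <- vapply(cfg$splits, function(s) as.integer(s$subjects), integer(1))
  total_trials <- sum(n_subjects) * length(cfg$labels) * cfg$trials_per_class
  seeds <- derive_seeds(seed, total_trials + 1)
  rows <- list()
  subj_counter <- 0L
  trial_i <- 0L
  for (sp in split_names) {
    for (s in seq_len(n_subjects[[sp]])) {
      subj_counter <- subj_counter + 1L
      subject <- sprintf("S%03d", subj_counter)
      for (label in cfg$labels) {
        for (k in seq_len(cfg$trials_per_class)) {
          trial_i <- trial_i + 1L
          trial_seed <- seeds[trial_i]
          session <- cfg$sessions[((k - 1) %% length(cfg$sessions)) + 1]
          n_reps <- with_seed(trial_seed,
            sample(seq(cfg$n_reps[1], cfg$n_reps[2]), 1))
          if (label == "OTH") {
            rec <- simulate_others(
              duration_s = n_reps * 4, fs = cfg$fs, seed = trial_seed,
              subject_id = subject, session = session)
            truth_reps <- 0L
          } else {
            sim <- simulate_exercise(
              profiles[[label]], n_reps = n_reps, fs = cfg$fs, mode = session,
              seed = trial_seed, subject_id = subject)
            rec <- sim$recording
            truth_reps <- sim$truth$n_reps
          }
          fname <- sprintf("%s_%s_%d.csv", subject, session, k)
          path <- file.path(cfg$root, sp, label, fname)
          write_recording(rec, path)
          rows[[length(rows) + 1L]] <- data.frame(
            path = file.path(sp, label, fname), split = sp, label = label,
            subject = subject, session = session, n_reps = truth_reps,
            seed = trial_seed, stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(cfg$root, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
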