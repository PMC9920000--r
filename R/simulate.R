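#' Synthetic pocket-IMU gait simulator
#'
#' Generates raw smartphone IMU recordings of a six-minute walk with full
#' ground truth, emulating the data-collection protocol: self-selected speed,
#' phone free-oriented in a trouser pocket, a reported pain-onset time, and
#' occasional rest blocks. The Earth-frame vertical acceleration is a
#' step-frequency oscillation with its minima at heel contacts, plus a
#' positive impact transient after each contact (pocket-side contacts scaled
#' by `ipsilateral_gain`, which is what the left/right labeling rule
#' exploits) and a small negative push-off transient at each toe-off (the
#' feature the toe-off detector finds). The anterior-posterior channel mixes
#' step- and stride-frequency components; medio-lateral is low-amplitude
#' sway. Claudication is modeled as a change-point: after `pain_onset` the
#' stride time lengthens by `1/cadence_factor`, stride-time variability
#' scales by `variability_factor` and amplitudes by `amp_factor`. The whole
#' Earth-frame signal is rotated into the body frame by the phone
#' orientation (with a small stride-synchronous wobble), gravity is added,
#' the gyroscope reports the exact angular rate of the orientation
#' trajectory, the magnetometer the rotated Earth field, and all sensors get
#' white noise and timestamp jitter.
#'
#' @name synthetic_data
NULL

MAG_EARTH_UT <- c(0, -42, 22)  # Earth field: dip on Y (up), north on +Z

#' Simulator configuration
#'
#' @param duration walk length, seconds.
#' @param fs_nominal nominal sampling rate, Hz.
#' @param timestamp_jitter sd of timestamp jitter, seconds.
#' @param stride_time_mean,stride_time_cv stride time distribution.
#' @param stance_fraction stance phase as a fraction of the stride.
#' @param step_amp vertical step-oscillation amplitude, m/s^2.
#' @param step_impact_amp heel-strike transient amplitude, m/s^2.
#' @param ipsilateral_gain multiplier (>= 1) on pocket-side impact peaks.
#' @param pain_onset onset time in seconds, or `NULL` for a pain-free walk.
#' @param post_onset list: `cadence_factor` (< 1 slows cadence),
#'   `variability_factor` (> 1), `amp_factor`.
#' @param phone_orientation unit quaternion of the phone in the pocket.
#' @param wobble_deg amplitude of the stride-synchronous orientation wobble.
#' @param accel_noise_sd,gyro_noise_sd,mag_noise_sd sensor noise sds
#'   (m/s^2, rad/s, uT).
#' @param rest_blocks list of `c(start, duration)` rest periods, seconds.
#' @param seed RNG seed.
#' @return a `gait_sim_config` list.
#' @export
gait_sim_config <- function(duration = 360, fs_nominal = 50,
                            timestamp_jitter = 0.004,
                            stride_time_mean = 1.1, stride_time_cv = 0.04,
                            stance_fraction = 0.60,
                            step_amp = 3, step_impact_amp = 4,
                            ipsilateral_gain = 1.3,
                            pain_onset = NULL,
                            post_onset = list(cadence_factor = 0.9,
                                              variability_factor = 1.5,
                                              amp_factor = 0.85),
                            phone_orientation = c(1, 0, 0, 0),
                            wobble_deg = 3,
                            accel_noise_sd = 0.3, gyro_noise_sd = 0.02,
                            mag_noise_sd = 0.5,
                            rest_blocks = list(), seed = 1) {
  stopifnot(stance_fraction > 0, stance_fraction < 1,
            ipsilateral_gain >= 1, stride_time_mean > 0)
  if (length(rest_blocks) > 1) {
    rb <- do.call(rbind, rest_blocks)
    rb <- rb[order(rb[, 1]), , drop = FALSE]
    if (any(rb[-1, 1] < rb[-nrow(rb), 1] + rb[-nrow(rb), 2]))
      stop("rest blocks overlap")
  }
  cfg <- mget(names(formals()))
  cfg$phone_orientation <- quat_normalize(phone_orientation)
  class(cfg) <- "gait_sim_config"
  cfg
}

# Draw the stride/event timeline; returns per-stride data frame.
sim_events <- function(cfg) {
  onset <- if (is.null(cfg$pain_onset)) Inf else cfg$pain_onset
  in_rest <- function(t) {
    for (b in cfg$rest_blocks) if (t >= b[1] && t < b[1] + b[2]) return(b)
    NULL
  }
  t <- 1.0                           # lead-in before the first stride
  rows <- list()
  while (t < cfg$duration - 2 * cfg$stride_time_mean) {
    b <- in_rest(t)
    if (!is.null(b)) { t <- b[1] + b[2] + 0.5; next }
    post <- t >= onset
    mu <- cfg$stride_time_mean * (if (post) 1 / cfg$post_onset$cadence_factor else 1)
    cv <- cfg$stride_time_cv * (if (post) cfg$post_onset$variability_factor else 1)
    T_k <- max(0.5, stats::rnorm(1, mu, cv * mu))
    # the whole stride must clear any rest block
    b2 <- in_rest(t + T_k)
    if (!is.null(b2)) { t <- b2[1] + b2[2] + 0.5; next }
    s <- cfg$stance_fraction
    rows[[length(rows) + 1]] <- data.frame(
      rhc = t, lto = t + (s - 0.5) * T_k, lhc = t + 0.5 * T_k,
      rto = t + s * T_k, stride_time = T_k, post_onset = post)
    t <- t + T_k
  }
  do.call(rbind, rows)
}

#' Simulate one pocket-IMU walk
#'
#' @param cfg a `gait_sim_config`.
#' @return list with `raw` (a `raw_imu_recording`), `truth` (ground truth:
#'   heel-contact and toe-off times with sides, stride times, pain onset,
#'   phone orientation, rest blocks), and `earth_accel` (the noise-free
#'   Earth-frame dynamic acceleration template, n x 3, at the nominal rate).
#' @export
simulate_walk <- function(cfg) {
  stopifnot(inherits(cfg, "gait_sim_config"))
  set.seed(cfg$seed)
  ev <- sim_events(cfg)
  if (is.null(ev) || nrow(ev) < 3) stop("configuration yields fewer than 3 strides")
  fs <- cfg$fs_nominal
  n <- round(cfg$duration * fs)
  tt <- (seq_len(n) - 1) / fs

  # step phase: 0 at each heel contact, +1 per step
  contacts <- sort(c(ev$rhc, ev$lhc))
  phi <- stats::approx(contacts, seq_along(contacts) - 1, xout = tt,
                       rule = 2)$y

  amp <- rep(1, n)
  amp[tt >= (if (is.null(cfg$pain_onset)) Inf else cfg$pain_onset)] <-
    cfg$post_onset$amp_factor
  for (b in cfg$rest_blocks) amp[tt >= b[1] & tt < b[1] + b[2]] <- 0
  # no oscillation outside the stride sequence
  amp[tt < contacts[1] | tt > contacts[length(contacts)]] <- 0

  add_bump <- function(y, center, amplitude, width) {
    i <- which(tt >= center & tt < center + width)
    y[i] <- y[i] + amplitude * sin(pi * (tt[i] - center) / width)
    y
  }
  # double-bump vertical waveform: step-frequency oscillation with minima at
  # heel contacts, plus a second harmonic whose push-off valley falls at the
  # toe-off instant (phi_to steps after the contact)
  phi_to <- 2 * cfg$stance_fraction - 1
  y <- amp * (-cfg$step_amp * cos(2 * pi * phi) -
                2 * cos(4 * pi * (phi - phi_to)))
  w_imp <- 0.10                          # heel-strike rebound, ~100 ms
  w_spk <- 0.08                          # impact spike at the contact instant
  for (i in seq_len(nrow(ev))) {
    a_r <- amp_at(amp, tt, ev$rhc[i]); a_l <- amp_at(amp, tt, ev$lhc[i])
    for (s in list(c(ev$rhc[i], a_r * cfg$ipsilateral_gain), c(ev$lhc[i], a_l))) {
      # sharp downward spike centered at contact, then positive rebound
      y <- add_bump(y, s[1] - w_spk / 2, -0.75 * cfg$step_impact_amp * s[2], w_spk)
      y <- add_bump(y, s[1] + w_spk / 2, cfg$step_impact_amp * s[2], w_imp)
    }
    # broad ipsilateral body-lift lobe over the pocket-side step
    y <- add_bump(y, ev$rhc[i], 2 * (cfg$ipsilateral_gain - 1) * a_r,
                  0.5 * ev$stride_time[i])
  }
  z <- amp * (1.5 * cos(2 * pi * phi) + 0.8 * sin(pi * phi))
  x <- amp * 0.8 * sin(pi * phi + 0.5)
  earth <- cbind(x, y, z)

  # orientation: fixed pocket pose + stride-synchronous wobble about Earth X
  wob <- cfg$wobble_deg * pi / 180 * sin(pi * phi) * (amp > 0)
  Q <- t(vapply(seq_len(n), function(i)
    quat_multiply(quat_from_axis_angle(c(1, 0, 0), wob[i]),
                  cfg$phone_orientation), numeric(4)))

  body <- sim_body_signals(Q, earth, fs, cfg)
  ts <- tt + stats::rnorm(n, 0, cfg$timestamp_jitter)
  ts <- sort(ts); ts <- ts - ts[1]
  raw <- raw_imu_recording(ts, body$accel, body$gyro, body$mag,
                           meta = list(simulated = TRUE, fs_nominal = fs))
  truth <- list(
    heel_contacts = data.frame(
      time = c(ev$rhc, ev$lhc),
      side = rep(c("R", "L"), each = nrow(ev)))[order(c(ev$rhc, ev$lhc)), ],
    toe_offs = data.frame(
      time = c(ev$rto, ev$lto),
      side = rep(c("R", "L"), each = nrow(ev)))[order(c(ev$rto, ev$lto)), ],
    stride_times = ev$stride_time,
    post_onset = ev$post_onset,
    pain_onset = cfg$pain_onset,
    phone_orientation = cfg$phone_orientation,
    stance_fraction = cfg$stance_fraction,
    rest_blocks = cfg$rest_blocks,
    fs = fs
  )
  list(raw = raw, truth = truth, earth_accel = earth)
}

amp_at <- function(amp, tt, t0) {
  i <- findInterval(t0, tt)
  if (i < 1) amp[1] else amp[min(i, length(amp))]
}

# Body-frame sensor streams from an orientation sequence + Earth-frame
# dynamic acceleration.
sim_body_signals <- function(Q, earth, fs, cfg) {
  n <- nrow(Q)
  g <- c(0, GRAVITY_MS2, 0)
  accel <- t(vapply(seq_len(n), function(i)
    body_ref(Q[i, ], earth[i, ] + g), numeric(3)))
  mag <- t(vapply(seq_len(n), function(i)
    body_ref(Q[i, ], MAG_EARTH_UT), numeric(3)))
  gyro <- matrix(0, n, 3)
  for (i in seq_len(n - 1))
    gyro[i, ] <- quat_log_vec(quat_multiply(quat_conjugate(Q[i, ]),
                                            Q[i + 1, ])) * fs
  gyro[n, ] <- gyro[n - 1, ]
  list(accel = accel + stats::rnorm(3 * n, 0, cfg$accel_noise_sd),
       gyro = gyro + stats::rnorm(3 * n, 0, cfg$gyro_noise_sd),
       mag = mag + stats::rnorm(3 * n, 0, cfg$mag_noise_sd))
}

#' Simulate a stationary recording through a sequence of poses
#'
#' Holds each pose for its duration with slight orientation wobble and
#' sensor noise; pose changes are smooth 1 s rotations. Used to reproduce
#' the two pocket-rotation protocol checks (screen back/forward, horizontal
#' flips).
#'
#' @param poses list of unit quaternions (see [euler_to_quat()]).
#' @param durations seconds per pose.
#' @param fs sampling rate, Hz.
#' @param wobble_deg wobble amplitude, degrees.
#' @param accel_noise_sd,gyro_noise_sd,mag_noise_sd sensor noise sds.
#' @param transition_s pose-change duration, seconds.
#' @param seed RNG seed.
#' @return list with `raw` (a `raw_imu_recording`) and `truth` (pose
#'   schedule).
#' @export
simulate_static_poses <- function(poses, durations, fs = 50, wobble_deg = 1,
                                  accel_noise_sd = 0.15,
                                  gyro_noise_sd = 0.01, mag_noise_sd = 0.5,
                                  transition_s = 1, seed = 1) {
  stopifnot(length(poses) == length(durations))
  set.seed(seed)
  total <- sum(durations)
  n <- round(total * fs)
  tt <- (seq_len(n) - 1) / fs
  bounds <- cumsum(durations)
  Q <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    k <- findInterval(tt[i], c(0, bounds), rightmost.closed = TRUE)
    k <- min(k, length(poses))
    q <- poses[[k]]
    if (k < length(poses)) {
      # smooth transition into the next pose
      into <- tt[i] - (bounds[k] - transition_s)
      if (into > 0) q <- quat_slerp(poses[[k]], poses[[k + 1]],
                                    min(1, into / transition_s))
    }
    wob <- wobble_deg * pi / 180 * sin(2 * pi * 0.7 * tt[i])
    Q[i, ] <- quat_multiply(quat_from_axis_angle(c(0, 0, 1), wob), q)
  }
  cfg <- list(accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
              mag_noise_sd = mag_noise_sd)
  body <- sim_body_signals(Q, matrix(0, n, 3), fs, cfg)
  raw <- raw_imu_recording(tt, body$accel, body$gyro, body$mag,
                           meta = list(simulated = TRUE, fs_nominal = fs))
  list(raw = raw,
       truth = list(poses = poses, durations = durations, fs = fs))
}

#' Simulate a patient cohort
#'
#' Per-patient latent gait parameters (stride time, stance fraction,
#' amplitudes, pocket-side gain, post-onset effect sizes) are drawn once per
#' patient, so trials of the same patient are internally consistent — the
#' structure that makes patient-wise splits measurably harder than
#' record-wise ones. Per-trial pain-onset times and phone poses are drawn
#' independently.
#'
#' @param n_patients,trials_per_patient cohort size.
#' @param duration walk length per trial, seconds.
#' @param effect_scale scales the post-onset effects toward null: 1 keeps
#'   the drawn effects, 0 removes the claudication signal entirely.
#' @param seed RNG seed.
#' @param process `"pipeline"` runs the full sensor pipeline
#'   (resample, filter, fusion, rotation, walking detection) per trial;
#'   `"ideal"` builds the Earth-frame recording directly from the simulator
#'   template plus sensor noise, bypassing orientation estimation.
#' @return list of per-trial lists: `walk` (a `walk_record`) and `truth`.
#' @export
simulate_cohort <- function(n_patients, trials_per_patient = 2,
                            duration = 360, effect_scale = 1, seed = 1,
                            process = c("pipeline", "ideal")) {
  process <- match.arg(process)
  stopifnot(n_patients >= 1)
  set.seed(seed)
  out <- list()
  for (p in seq_len(n_patients)) {
    # wide between-patient baseline ranges and modest, patient-specific
    # post-onset effects: one patient's claudication gait overlaps another's
    # normal gait, so only record-wise splits (overlapping windows on both
    # sides) make the problem easy
    lat <- list(
      stride = stats::runif(1, 0.95, 1.35),
      cv = stats::runif(1, 0.02, 0.08),
      stance = min(0.66, max(0.54, stats::rnorm(1, 0.60, 0.02))),
      amp = stats::runif(1, 0.6, 1.5),
      gain = stats::runif(1, 1.15, 1.45),
      cadence_f = stats::runif(1, 0.85, 0.97),
      var_f = stats::runif(1, 1.1, 1.6),
      amp_f = stats::runif(1, 0.8, 1.0)
    )
    for (tr in seq_len(trials_per_patient)) {
      onset <- stats::runif(1, 0.35, 0.65) * duration
      pose <- euler_to_quat(roll = stats::runif(1, -45, 45),
                            pitch = stats::runif(1, -45, 45),
                            yaw = stats::runif(1, -180, 180))
      cfg <- gait_sim_config(
        duration = duration,
        stride_time_mean = lat$stride, stride_time_cv = lat$cv,
        stance_fraction = lat$stance,
        step_amp = 3 * lat$amp, step_impact_amp = 4 * lat$amp,
        ipsilateral_gain = lat$gain,
        pain_onset = onset,
        post_onset = list(
          cadence_factor = 1 - effect_scale * (1 - lat$cadence_f),
          variability_factor = 1 + effect_scale * (lat$var_f - 1),
          amp_factor = 1 - effect_scale * (1 - lat$amp_f)),
        phone_orientation = pose,
        seed = sample.int(2^30, 1))
      sim <- simulate_walk(cfg)
      walk <- if (process == "pipeline")
        process_trial(sim$raw, patient_id = sprintf("P%02d", p),
                      trial_id = sprintf("T%d", tr), pain_onset = onset)
      else ideal_walk_record(sim, patient_id = sprintf("P%02d", p),
                             trial_id = sprintf("T%d", tr),
                             pain_onset = onset, cfg = cfg)
      out[[length(out) + 1]] <- list(walk = walk, truth = sim$truth)
    }
  }
  out
}

# Earth-frame walk record straight from the simulator template (adds sensor
# noise, skips orientation estimation).
ideal_walk_record <- function(sim, patient_id, trial_id, pain_onset, cfg) {
  ae <- sim$earth_accel +
    stats::rnorm(length(sim$earth_accel), 0, cfg$accel_noise_sd)
  fs <- cfg$fs_nominal
  for (j in 1:3) ae[, j] <- butterworth_lowpass(ae[, j], fs)
  earth <- structure(list(rate = fs, accel_earth = ae,
                          gravity_removed = TRUE, warmup_samples = integer(0)),
                     class = "earth_frame_recording")
  mask <- detect_walking(
    acceleration_magnitude(cbind(ae[, 1], ae[, 2] + GRAVITY_MS2, ae[, 3])), fs)
  walk_record(patient_id, trial_id, earth, mask, pain_onset)
}
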