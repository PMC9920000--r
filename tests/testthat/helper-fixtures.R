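# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# One 120 s simulated walk (no pain onset) pushed through the full sensor
# pipeline, with per-window gait events attached.
walk_fixture <- function() {
  memo("walk120", {
    cfg <- gait_sim_config(duration = 120, pain_onset = NULL, seed = 3,
                           phone_orientation = euler_to_quat(20, 80, -60))
    sim <- simulate_walk(cfg)
    walk <- process_trial(sim$raw, "P1", "T1")
    windows <- drop_cycleless(attach_window_events(make_windows(walk)))
    list(cfg = cfg, sim = sim, walk = walk, windows = windows)
  })
}

# Detected heel-contact times (seconds, absolute) of a windowed walk.
detected_contact_times <- function(windows, fs = 50) {
  sort(unique(unlist(lapply(windows, function(w)
    (attr(w, "start_index") + c(w$events$rhc, w$events$lhc) - 2) / fs))))
}

# A 360 s Earth-frame recording built directly (no sensor pipeline): used for
# windowing arithmetic.
earth_360_fixture <- function() {
  memo("earth360", {
    fs <- 50
    t <- seq(0, 360 - 1 / fs, by = 1 / fs)
    ae <- cbind(0.3 * sin(2 * pi * 0.9 * t),
                3 * sin(2 * pi * 1.8 * t),
                sin(2 * pi * 0.9 * t + 1))
    colnames(ae) <- c("x", "y", "z")
    earth <- structure(list(rate = fs, accel_earth = ae,
                            gravity_removed = TRUE,
                            warmup_samples = integer(0)),
                       class = "earth_frame_recording")
    walk_record("P1", "T1", earth)
  })
}

# Random window_signals with synthetic events, for feature oracles.
random_window <- function(seed, fs = 50, n = 500) {
  set.seed(seed)
  ev <- gait_events(rhc = sort(sample(1:n, 5)), fs = fs)
  window_signals(ax = rnorm(n), ay = rnorm(n, sd = 2), az = rnorm(n),
                 fs = fs, events = ev)
}

# Cohort dataset with per-patient idiosyncrasies ("ideal" Earth-frame
# processing), shared between classifier tests and the acceptance suite.
cohort_dataset <- function() {
  memo("cohort_ds", {
    trials <- simulate_cohort(n_patients = 12, trials_per_patient = 2,
                              duration = 120, seed = 42, process = "ideal")
    assemble_dataset(lapply(trials, `[[`, "walk"))
  })
}
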