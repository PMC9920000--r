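# claudigait

Detecting the onset of intermittent claudication (IC) from a smartphone in a
trouser pocket.

Peripheral arterial disease narrows the lower-limb arteries; during walking
the calf muscles outgrow their blood supply and patients develop exercise
pain — intermittent claudication — that forces them to slow down or stop.
The gait change is visible in inertial data. `claudigait` implements an
end-to-end pipeline that turns a raw phone sensor log of a six-minute walk
test into a binary per-window IC classification:

1. **Ingestion** — CSV logs (one row per sample: timestamp + triaxial
   accelerometer, gyroscope, magnetometer) with irregular OS-driven
   timing, linearly resampled onto a uniform 50 Hz grid.
2. **Filtering** — zero-phase 4th-order Butterworth low-pass at 5 Hz
   (human walking kinematics live below ~4 Hz).
3. **Orientation** — Madgwick gradient-descent fusion of the three sensors
   estimates a per-sample quaternion; acceleration is rotated into an
   Earth-fixed frame (X medio-lateral, Y vertical, Z anterior–posterior),
   so the phone's free pocket pose stops mattering.
4. **Walking detection** — samples whose rolling standard deviation of the
   acceleration magnitude stays below 1 m/s² are rest and are excluded.
5. **Gait events** — singular spectrum analysis (SSA) detrends the vertical
   and anterior–posterior channels; minima of the dominant stride-periodic
   oscillation, refined by the minimum of the Y·Z product, give heel
   contacts; a mean-amplitude rule assigns left/right; toe-offs are the
   qualifying extrema between contacts.
6. **Features** — 10 s windows with 50% overlap; each window yields 155
   features: 70 time-domain (statistics, 10-bin histograms, RMS ratios
   RMSRᵢ = RMSᵢ/RMS_T, signal magnitude area, kurtosis m₄/m₂²,
   skewness m₃/m₂^{3/2}, LCSS cycle similarity, cadence, stride time,
   swing/stance ratio) and 85 frequency-domain (Welch PSD summaries,
   normalized spectral entropy, spectral energy Σ|Xₖ|²/N, 40 FFT and 40
   DCT coefficients covering 0.1–4.0 Hz).
7. **Classification** — tree ensembles (gradient boosting in two
   configurations, random forest, extra-trees) with 10-fold
   cross-validation, compared under two split strategies: **record-wise**
   (windows split independently) and **patient-wise** (whole patients held
   out). The gap between the two measures how much a model relies on
   patient identity rather than a generalizable IC signature.

Because clinical recordings of this kind are private, the package ships a
**synthetic pocket-IMU gait simulator** with full ground truth (heel
contact and toe-off times with sides, stride times, pain onset, phone
pose, rest blocks). Claudication is modeled as a change-point: after the
reported pain onset, cadence drops, stride variability rises and
amplitudes shrink, with per-patient latent parameters so that cohorts
reproduce the structure that makes patient-wise splits hard.

## Worked example

```r
library(claudigait)

# simulate one 2-minute walk with pain onset at 60 s, phone tilted in pocket
cfg <- gait_sim_config(duration = 120, pain_onset = 60, seed = 3,
                       phone_orientation = euler_to_quat(20, 80, -60))
sim <- simulate_walk(cfg)

# full sensor pipeline: resample, filter, fuse, rotate, mask rest
walk <- process_trial(sim$raw, patient_id = "P1", trial_id = "T1",
                      pain_onset = 60)

windows <- drop_cycleless(attach_window_events(make_windows(walk)))
length(windows)
#> [1] 21
mean(unlist(lapply(windows, function(w) w$cycles$stride_time)))
#> [1] 1.158734
mean(sim$truth$stride_times)   # simulator ground truth
#> [1] 1.159504
features <- window_features(windows[[1]])
length(features)
#> [1] 155
```

The 21 windows are the 10 s / 50% overlap slots that survive the 5 s
orientation warmup and the walking mask. The detected mean stride time
(1.1587 s) recovers the ground truth (1.1595 s) to under a millisecond —
the walk mixes 1.1 s pre-onset strides with the slower post-onset strides,
and the detector tracks both. A cohort-level experiment:

```r
trials <- simulate_cohort(n_patients = 12, trials_per_patient = 2,
                          duration = 120, seed = 42, process = "ideal")
ds <- assemble_dataset(lapply(trials, `[[`, "walk"))
rec <- evaluate_model("xgboost", ds, split_records(ds, seed = 19), seed = 3)
pat <- evaluate_model("xgboost", ds, split_patients(ds, seed = 19), seed = 3)
round(c(record = rec[["accuracy"]], patient = pat[["accuracy"]]), 3)
#>  record patient
#>   1.000   0.773
```

Record-wise accuracy comes out higher than patient-wise accuracy on this
cohort: overlapping windows place near-duplicates on both sides of a
record-wise split, while patient-wise evaluation must generalize across
patients whose claudication signatures differ.

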