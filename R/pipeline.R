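#' End-to-end pipeline orchestration
#'
#' Runs the full chain — ingestion, resampling, filtering, orientation
#' fusion, Earth-frame rotation, walking detection, windowing, gait events,
#' feature extraction, labeling, classification — with one nested config, a
#' single global seed fanned out to per-stage seeds by stable hashing, and a
#' JSON run manifest recording per-stage counts.
#'
#' @name cli_pipeline
NULL

PIPELINE_DEFAULTS <- list(
  seed = 1,
  simulate = list(n_patients = 8, trials_per_patient = 2, duration = 120,
                  effect_scale = 1, process = "pipeline"),
  input_csv = NULL,            # optional named list patient/trial/onset/path
  resample = list(rate = 50),
  filter = list(cutoff_hz = 5, order = 4),
  walk = list(threshold_ms2 = 1.0, window_s = 1.0, min_walk_s = 2.0),
  fusion = list(beta = 0.1, warmup_s = 5, remove_gravity = TRUE),
  windows = list(window_s = 10, overlap = 0.5, na_action = "drop"),
  classify = list(split = "records", test_frac = 0.2, k = 10,
                  models = "all")
)

#' Build a validated pipeline configuration
#'
#' @param ... overrides of the defaults, nested lists merged key-wise.
#'   Unknown keys are rejected.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- merge_config(PIPELINE_DEFAULTS, list(...))
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(base, override, path = "") {
  unknown <- setdiff(names(override), names(base))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) && !is.null(names(base[[k]])))
      base[[k]] <- merge_config(base[[k]], override[[k]], paste0(path, k, "."))
    else base[[k]] <- override[[k]]
  }
  base
}

# Per-stage seed derived from the global seed by stable hashing.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (seed * 7919 + h * 104729) %% 2147483647
}

#' Process one raw recording into a walk record
#'
#' Resample to the uniform grid, low-pass filter, estimate orientation,
#' rotate to the Earth frame, detect walking.
#'
#' @param raw a `raw_imu_recording`.
#' @param patient_id,trial_id identifiers.
#' @param pain_onset onset time, seconds, or `NULL`.
#' @param cfg a `pipeline_config` (defaults used when omitted).
#' @return a `walk_record`.
#' @export
process_trial <- function(raw, patient_id, trial_id, pain_onset = NULL,
                          cfg = pipeline_config()) {
  u <- resample_linear(raw, rate = cfg$resample$rate)
  u <- filter_recording(u, cutoff = cfg$filter$cutoff_hz,
                        order = cfg$filter$order)
  ori <- estimate_orientation(u, beta = cfg$fusion$beta,
                              warmup = cfg$fusion$warmup_s)
  earth <- rotate_to_earth(u, ori,
                           remove_gravity = cfg$fusion$remove_gravity)
  mag_for_mask <- if (earth$gravity_removed)
    acceleration_magnitude(cbind(earth$accel_earth[, 1],
                                 earth$accel_earth[, 2] + GRAVITY_MS2,
                                 earth$accel_earth[, 3]))
  else acceleration_magnitude(earth$accel_earth)
  mask <- detect_walking(mag_for_mask, earth$rate,
                         threshold = cfg$walk$threshold_ms2,
                         window = cfg$walk$window_s,
                         min_walk = cfg$walk$min_walk_s)
  walk_record(patient_id, trial_id, earth, mask, pain_onset)
}

#' Run the pipeline end to end
#'
#' With `cfg$input_csv` unset, a cohort is simulated; otherwise the listed
#' CSV logs are read. Produces the window dataset, the model-comparison
#' report, and a manifest with per-stage accounting
#' (trials in, windows created, dropped, retained, labeled per class).
#'
#' @param cfg a `pipeline_config`.
#' @return list with `dataset`, `report`, `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$input_csv)) {
    trials <- simulate_cohort(
      n_patients = cfg$simulate$n_patients,
      trials_per_patient = cfg$simulate$trials_per_patient,
      duration = cfg$simulate$duration,
      effect_scale = cfg$simulate$effect_scale,
      seed = stage_seed(cfg$seed, "simulate"),
      process = cfg$simulate$process)
    walks <- lapply(trials, `[[`, "walk")
  } else {
    walks <- lapply(cfg$input_csv, function(spec) {
      process_trial(read_imu_csv(spec$path), spec$patient_id, spec$trial_id,
                    spec$pain_onset, cfg)
    })
  }
  ds <- assemble_dataset(walks, window_s = cfg$windows$window_s,
                         overlap = cfg$windows$overlap,
                         na_action = cfg$windows$na_action)
  plan <- if (cfg$classify$split == "patients")
    split_patients(ds, cfg$classify$test_frac,
                   seed = stage_seed(cfg$seed, "split"))
  else split_records(ds, cfg$classify$test_frac,
                     seed = stage_seed(cfg$seed, "split"))
  report <- compare_models(ds, plan, models = cfg$classify$models,
                           k = cfg$classify$k,
                           seed = stage_seed(cfg$seed, "train"))
  created <- sum(ds$accounting$created)
  dropped <- sum(ds$accounting$dropped_cycleless)
  manifest <- list(
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    trials_in = length(walks),
    windows_created = created,
    windows_dropped_cycleless = dropped,
    windows_dropped_incomplete = ds$n_incomplete,
    windows_retained = nrow(ds$features),
    labels = as.list(table(ds$labels))
  )
  stopifnot(manifest$windows_created ==
              manifest$windows_retained + manifest$windows_dropped_cycleless +
              if (cfg$windows$na_action == "drop") manifest$windows_dropped_incomplete else 0L)
  list(dataset = ds, report = report, manifest = manifest)
}

#' Write a run manifest as JSON
#'
#' @param manifest manifest list from [run_pipeline()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
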