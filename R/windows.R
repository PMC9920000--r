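#' Windowing, labeling and dataset assembly
#'
#' Walks are sliced into 10 s windows with 50% overlap. Windows are anchored
#' within each maximal walking run of the walk mask, so rest periods create
#' no phantom windows; a rest-free recording of duration D yields
#' `floor((D - window_s) / ((1 - overlap) * window_s)) + 1` windows. Each
#' window is labeled 1 (claudication present) iff at least half of it lies
#' at or after the patient-reported pain onset.
#'
#' @name windows_dataset
NULL

#' Bundle one processed walk
#'
#' @param patient_id,trial_id identifiers.
#' @param earth an `earth_frame_recording`.
#' @param walk_mask a `walk_mask` aligned with `earth` (default: all
#'   walking).
#' @param pain_onset onset time in seconds from recording start, or `NULL`.
#' @return a `walk_record`.
#' @export
walk_record <- function(patient_id, trial_id, earth, walk_mask = NULL,
                        pain_onset = NULL) {
  stopifnot(inherits(earth, "earth_frame_recording"))
  n <- nrow(earth$accel_earth)
  if (is.null(walk_mask)) walk_mask <- new_walk_mask(rep(TRUE, n))
  stopifnot(length(walk_mask$walking) == n)
  dur <- n / earth$rate
  if (!is.null(pain_onset) && (pain_onset < 0 || pain_onset > dur))
    stop("pain_onset outside the recording")
  structure(list(patient_id = patient_id, trial_id = trial_id,
                 earth = earth, walk_mask = walk_mask,
                 pain_onset = pain_onset),
            class = "walk_record")
}

#' Slice a walk into overlapping windows
#'
#' @param walk a `walk_record`.
#' @param window_s window length, seconds.
#' @param overlap fractional overlap in [0, 1).
#' @param exclude_warmup drop windows overlapping the orientation warmup?
#' @return list of `window_signals` (without events; see
#'   [attach_window_events()]), each carrying attributes `start_s` and
#'   `start_index`.
#' @export
make_windows <- function(walk, window_s = 10, overlap = 0.5,
                         exclude_warmup = TRUE) {
  stopifnot(inherits(walk, "walk_record"), overlap >= 0, overlap < 1)
  fs <- walk$earth$rate
  wlen <- round(window_s * fs)
  stride <- round((1 - overlap) * window_s * fs)
  ae <- walk$earth$accel_earth
  first_ok <- if (exclude_warmup && length(walk$earth$warmup_samples))
    max(walk$earth$warmup_samples) + 1L else 1L
  out <- list()
  seg <- walk$walk_mask$segments
  for (si in seq_len(nrow(seg))) {
    lo <- max(seg[si, "start"], first_ok); hi <- seg[si, "end"]
    if (hi - lo + 1 < wlen) next
    for (s0 in seq(lo, hi - wlen + 1, by = stride)) {
      idx <- s0:(s0 + wlen - 1)
      w <- window_signals(ax = ae[idx, 1], ay = ae[idx, 2], az = ae[idx, 3],
                          fs = fs)
      attr(w, "start_index") <- s0
      attr(w, "start_s") <- (s0 - 1) / fs
      out[[length(out) + 1]] <- w
    }
  }
  out
}

#' Run gait-event detection on each window
#'
#' @param windows list of `window_signals` from [make_windows()].
#' @param L SSA embedding length, samples.
#' @return the windows with `events` and `cycles` filled in.
#' @export
attach_window_events <- function(windows, L = NULL) {
  lapply(windows, function(w) {
    LL <- if (is.null(L)) round(2 * w$fs) else L
    ev <- detect_gait_events(w$ay, w$az, w$fs, L = LL)
    w$events <- ev
    w$cycles <- segment_cycles(ev)
    w
  })
}

#' Drop windows with no complete gait cycle
#'
#' @param windows list of `window_signals` with events attached.
#' @return list with attributes `n_dropped` recorded on the result.
#' @export
drop_cycleless <- function(windows) {
  keep <- vapply(windows, function(w) nrow(w$cycles) > 0, logical(1))
  out <- windows[keep]
  attr(out, "n_dropped") <- sum(!keep)
  if (length(out) == 0 && length(windows) > 0)
    warning("all windows dropped: no gait cycles detected")
  out
}

#' Label one window from the pain onset
#'
#' @param start window start, seconds.
#' @param window_s window length, seconds.
#' @param pain_onset onset time in seconds, or `NULL`.
#' @return 1 iff at least 50% of the window lies at or after the onset,
#'   else 0.
#' @export
label_window <- function(start, window_s, pain_onset = NULL) {
  if (is.null(pain_onset)) return(0L)
  as.integer(pain_onset <= start + window_s / 2)
}

#' Assemble the ML-ready window dataset
#'
#' Runs the per-window pipeline (events, 155 features, label) over a list of
#' walks and stacks rows. Rows with flagged-missing features are dropped
#' (`na_action = "drop"`) or median-imputed per feature
#' (`na_action = "impute"`); counts are recorded.
#'
#' @param walks list of `walk_record`.
#' @param window_s,overlap windowing parameters.
#' @param na_action `"drop"` or `"impute"`.
#' @return a `window_dataset`: list with `features` (matrix, 155 named
#'   columns), `labels` (0/1), `patient_ids`, `trial_ids`, `window_start_s`,
#'   and `accounting` (per-walk created/dropped counts).
#' @export
assemble_dataset <- function(walks, window_s = 10, overlap = 0.5,
                             na_action = c("drop", "impute")) {
  na_action <- match.arg(na_action)
  stopifnot(length(walks) >= 1)
  rows <- list(); labs <- integer(0); pids <- c(); tids <- c(); starts <- c()
  acct <- data.frame(patient_id = character(0), trial_id = character(0),
                     created = integer(0), dropped_cycleless = integer(0))
  for (walk in walks) {
    ws <- make_windows(walk, window_s, overlap)
    ws <- attach_window_events(ws)
    kept <- drop_cycleless(ws)
    acct <- rbind(acct, data.frame(
      patient_id = walk$patient_id, trial_id = walk$trial_id,
      created = length(ws), dropped_cycleless = attr(kept, "n_dropped")))
    for (w in kept) {
      rows[[length(rows) + 1]] <- window_features(w)
      labs <- c(labs, label_window(attr(w, "start_s"), window_s,
                                   walk$pain_onset))
      pids <- c(pids, walk$patient_id)
      tids <- c(tids, walk$trial_id)
      starts <- c(starts, attr(w, "start_s"))
    }
  }
  if (length(rows) == 0) stop("zero retained windows across all walks")
  X <- do.call(rbind, rows)
  n_na <- sum(!stats::complete.cases(X))
  if (na_action == "drop") {
    ok <- stats::complete.cases(X)
    X <- X[ok, , drop = FALSE]; labs <- labs[ok]; pids <- pids[ok]
    tids <- tids[ok]; starts <- starts[ok]
    if (nrow(X) == 0) stop("zero retained windows after dropping incomplete rows")
  } else {
    for (j in which(colSums(is.na(X)) > 0)) {
      med <- stats::median(X[, j], na.rm = TRUE)
      X[is.na(X[, j]), j] <- med
    }
  }
  structure(list(features = X, labels = labs, patient_ids = pids,
                 trial_ids = tids, window_start_s = starts,
                 accounting = acct, n_incomplete = n_na),
            class = "window_dataset")
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf("<window_dataset> %d windows x %d features, %d patients, class balance %.2f\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$patient_ids)), mean(x$labels)))
  invisible(x)
}

#' Write / read a window dataset as CSV + JSON schema sidecar
#'
#' @param ds a `window_dataset`.
#' @param path CSV output path; the schema goes to `<path>.schema.json`.
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "window_dataset"))
  df <- data.frame(patient_id = ds$patient_ids, trial_id = ds$trial_ids,
                   window_start_s = ds$window_start_s, label = ds$labels,
                   ds$features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(feature_schema(), paste0(path, ".schema.json"))
  invisible(path)
}

#' @rdname write_dataset_csv
#' @param path CSV path written by [write_dataset_csv()].
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("patient_id", "trial_id", "window_start_s", "label")
  X <- as.matrix(df[, setdiff(names(df), meta)])
  structure(list(features = X, labels = as.integer(df$label),
                 patient_ids = df$patient_id, trial_ids = df$trial_id,
                 window_start_s = df$window_start_s,
                 accounting = NULL, n_incomplete = 0L),
            class = "window_dataset")
}
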