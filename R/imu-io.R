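#' Raw and uniform IMU recordings
#'
#' Smartphone sensor loggers emit one CSV row per sample with a timestamp and
#' three columns per sensor. Sampling is nominally 50 Hz but the OS delivers
#' events at irregular intervals, so raw logs carry irregular timestamps and
#' are linearly resampled onto a uniform grid before any filtering.
#'
#' @name imu_io
NULL

IMU_COLUMNS <- c("timestamp", "acc_x", "acc_y", "acc_z",
                 "gyr_x", "gyr_y", "gyr_z", "mag_x", "mag_y", "mag_z")

#' Construct a raw IMU recording
#'
#' @param timestamps sample times in seconds, irregular spacing allowed.
#' @param accel,gyro,mag n x 3 matrices (m/s^2, rad/s, uT), body frame.
#' @param meta free-form named list (device, nominal rate, bookkeeping).
#' @return a `raw_imu_recording`. Duplicate timestamps keep the last sample
#'   (OS-batched sensor events overwrite); timestamps are strictly increasing
#'   afterwards.
#' @export
raw_imu_recording <- function(timestamps, accel, gyro, mag, meta = list()) {
  accel <- as_mat3(accel, "accel"); gyro <- as_mat3(gyro, "gyro")
  mag <- as_mat3(mag, "mag")
  n <- length(timestamps)
  if (nrow(accel) != n || nrow(gyro) != n || nrow(mag) != n)
    stop("sensor arrays must have one row per timestamp")
  o <- order(timestamps)
  timestamps <- timestamps[o]
  accel <- accel[o, , drop = FALSE]; gyro <- gyro[o, , drop = FALSE]
  mag <- mag[o, , drop = FALSE]
  keep <- !duplicated(timestamps, fromLast = TRUE)   # last sample wins
  if (!all(keep)) meta$dropped_duplicates <- sum(!keep)
  structure(list(
    timestamps = timestamps[keep],
    accel = accel[keep, , drop = FALSE],
    gyro = gyro[keep, , drop = FALSE],
    mag = mag[keep, , drop = FALSE],
    meta = meta
  ), class = "raw_imu_recording")
}

as_mat3 <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop(sprintf("%s must have 3 columns", what))
  storage.mode(x) <- "double"
  unname(x)
}

#' Read a smartphone IMU CSV log
#'
#' Default dialect: header `timestamp, acc_x, acc_y, acc_z, gyr_x, gyr_y,
#' gyr_z, mag_x, mag_y, mag_z`, units m/s^2 / rad/s / uT. The timestamp unit
#' is auto-detected from the median spacing (spacing > 1 is taken as
#' milliseconds, the unit phone loggers write) and recorded in `meta`. Rows
#' with unparseable cells are dropped and counted in `meta$dropped_rows`.
#'
#' @param path CSV file path.
#' @param dialect optional list: `columns` (named mapping from the canonical
#'   names in `IMU_COLUMNS` to file column names), `header` (logical).
#' @return a `raw_imu_recording`.
#' @export
read_imu_csv <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = !identical(dialect$header, FALSE),
                        stringsAsFactors = FALSE)
  cols <- IMU_COLUMNS
  cols_file <- vapply(cols, function(cn) {
    if (!is.null(dialect$columns[[cn]])) dialect$columns[[cn]] else cn
  }, character(1))
  absent <- setdiff(cols_file, names(df))
  if (length(absent))
    stop("missing required column(s): ", paste(absent, collapse = ", "))
  m <- as.matrix(df[, cols_file])
  suppressWarnings(storage.mode(m) <- "double")   # bad cells become NA
  bad <- rowSums(is.na(m)) > 0
  m <- m[!bad, , drop = FALSE]
  if (nrow(m) < 2) stop("fewer than 2 valid rows in ", path)
  ts <- m[, 1]
  unit <- if (stats::median(diff(sort(ts))) > 1) "ms" else "s"
  if (unit == "ms") ts <- ts / 1000
  raw_imu_recording(
    ts, m[, 2:4], m[, 5:7], m[, 8:10],
    meta = list(source = path, timestamp_unit = unit,
                dropped_rows = sum(bad))
  )
}

#' Write a recording in the IMU CSV dialect
#'
#' Emits the default dialect with fixed 6-decimal formatting (timestamps in
#' milliseconds) so that simulator output round-trips through
#' [read_imu_csv()] to float precision.
#'
#' @param rec a `raw_imu_recording`.
#' @param path output path.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "raw_imu_recording"))
  m <- cbind(rec$timestamps * 1000, rec$accel, rec$gyro, rec$mag)
  lines <- apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = ","))
  writeLines(c(paste(IMU_COLUMNS, collapse = ","), lines), path)
  invisible(path)
}

#' Resample an irregular recording onto a uniform grid
#'
#' Linear interpolation of every channel onto `start + k/rate`,
#' k = 0..K-1, clipped to the observed span (no extrapolation), giving
#' `floor(span * rate) + 1` samples. Each channel is interpolated
#' independently onto the one shared grid.
#'
#' @param raw a `raw_imu_recording`.
#' @param rate target rate, Hz (default 50).
#' @return a `uniform_imu_recording`: list with `rate`, `start_time`,
#'   `accel`, `gyro`, `mag`.
#' @export
resample_linear <- function(raw, rate = 50) {
  stopifnot(inherits(raw, "raw_imu_recording"))
  ts <- raw$timestamps
  if (length(ts) < 2) stop("need at least 2 samples to resample")
  if (any(diff(ts) <= 0)) stop("timestamps must be strictly increasing")
  span <- ts[length(ts)] - ts[1]
  if (span < 1 / rate) stop("recording span shorter than one sample period")
  grid <- ts[1] + seq(0, floor(span * rate + 1e-9)) / rate
  interp <- function(M) {
    out <- vapply(1:3, function(j)
      stats::approx(ts, M[, j], xout = grid, method = "linear",
                    ties = "ordered")$y,
      numeric(length(grid)))
    unname(out)
  }
  structure(list(
    rate = rate,
    start_time = ts[1],
    accel = interp(raw$accel),
    gyro = interp(raw$gyro),
    mag = interp(raw$mag)
  ), class = "uniform_imu_recording")
}

#' @export
print.raw_imu_recording <- function(x, ...) {
  cat(sprintf("<raw_imu_recording> %d samples spanning %.2f s (irregular)\n",
              length(x$timestamps),
              diff(range(x$timestamps))))
  invisible(x)
}

#' @export
print.uniform_imu_recording <- function(x, ...) {
  cat(sprintf("<uniform_imu_recording> %d samples at %g Hz (%.2f s)\n",
              nrow(x$accel), x$rate, (nrow(x$accel) - 1) / x$rate))
  invisible(x)
}
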