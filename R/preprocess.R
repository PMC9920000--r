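#' Low-pass filtering and walking detection
#'
#' Human walking kinematics live below about 4 Hz, so every inertial channel
#' is low-pass filtered with a fourth-order Butterworth at 5 Hz before any
#' later stage. Filtering is zero-phase (forward-backward), so gait-event
#' timing is not shifted. Rest segments are found by thresholding the rolling
#' standard deviation of the acceleration magnitude: at rest it stays under
#' 1 m/s^2.
#'
#' @name preprocess
NULL

#' Zero-phase Butterworth low-pass filter
#'
#' @param channel numeric signal sampled uniformly at `fs`.
#' @param fs sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz (must be below fs/2).
#' @param order filter order (applied forward and backward, so the effective
#'   magnitude response is squared).
#' @return filtered signal, same length as input.
#' @export
butterworth_lowpass <- function(channel, fs, cutoff = 5, order = 4) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  n <- length(channel)
  if (n <= 3 * (order + 1))
    stop("signal too short for the requested filter order")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # odd-reflection padding suppresses the forward-backward edge transients
  pad <- min(n - 1, max(3 * (2 * order + 1), 10 * ceiling(fs / cutoff)))
  head_pad <- 2 * channel[1] - channel[(pad + 1):2]
  tail_pad <- 2 * channel[n] - channel[(n - 1):(n - pad)]
  out <- signal::filtfilt(bf, c(head_pad, channel, tail_pad))
  as.numeric(out[(pad + 1):(pad + n)])
}

#' Apply the low-pass filter to every channel of a uniform recording
#'
#' @param rec a `uniform_imu_recording`.
#' @inheritParams butterworth_lowpass
#' @return the recording with all accel/gyro/mag channels filtered.
#' @export
filter_recording <- function(rec, cutoff = 5, order = 4) {
  stopifnot(inherits(rec, "uniform_imu_recording"))
  f <- function(M) apply(M, 2, butterworth_lowpass, fs = rec$rate,
                         cutoff = cutoff, order = order)
  rec$accel <- f(rec$accel); rec$gyro <- f(rec$gyro); rec$mag <- f(rec$mag)
  rec
}

#' Euclidean magnitude of a 3-axis series
#'
#' @param accel n x 3 matrix.
#' @return length-n vector of per-sample norms.
#' @export
acceleration_magnitude <- function(accel) {
  accel <- as_mat3(accel, "accel")
  sqrt(rowSums(accel^2))
}

#' Detect walking vs. rest from the acceleration magnitude
#'
#' A sample is walking iff the centered rolling standard deviation (window
#' `window` seconds) of the magnitude is at least `threshold`; walking runs
#' shorter than `min_walk` seconds are relabeled rest.
#'
#' @param magnitude acceleration-magnitude series (filtered), m/s^2.
#' @param fs sampling rate, Hz.
#' @param threshold rest/walk threshold on the rolling std, m/s^2.
#' @param window rolling window length, seconds.
#' @param min_walk minimum duration of a walking run, seconds.
#' @return a `walk_mask`: list with `walking` (logical per sample) and
#'   `segments` (matrix of start/end sample indices of walking runs).
#' @export
detect_walking <- function(magnitude, fs, threshold = 1.0, window = 1.0,
                           min_walk = 2.0) {
  w <- round(window * fs)
  if (w < 2) stop("window * fs must be at least 2")
  n <- length(magnitude)
  if (n < w) {
    warning("series shorter than one rolling window; marking all rest")
    return(new_walk_mask(rep(FALSE, n)))
  }
  rsd <- zoo::rollapply(magnitude, width = w, FUN = stats::sd,
                        fill = NA, align = "center", partial = TRUE)
  walking <- !is.na(rsd) & rsd >= threshold
  # suppress walking runs shorter than min_walk
  r <- rle(walking)
  short <- r$values & r$lengths < round(min_walk * fs)
  r$values[short] <- FALSE
  new_walk_mask(inverse.rle(r))
}

new_walk_mask <- function(walking) {
  r <- rle(walking)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- cbind(start = starts[r$values], end = ends[r$values])
  structure(list(walking = walking, segments = seg), class = "walk_mask")
}

#' @export
print.walk_mask <- function(x, ...) {
  cat(sprintf("<walk_mask> %d/%d samples walking in %d segment(s)\n",
              sum(x$walking), length(x$walking), nrow(x$segments)))
  invisible(x)
}
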