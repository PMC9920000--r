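#' Time-domain gait features (70 per window)
#'
#' One 10 s window yields 70 time-domain features over the acceleration
#' magnitude and the three Earth-frame components: 5 basic statistics x 4
#' signals, a 10-bin histogram x 4 signals, 3 RMS ratios, signal magnitude
#' area, kurtosis and skewness of the magnitude, LCSS cycle similarity,
#' cadence, mean stride time and the swing/stance ratio. Feature order is
#' fixed; [feature_schema()] exports it.
#'
#' @name features_time
NULL

SIGNAL_NAMES <- c("mag", "ax", "ay", "az")

#' Bundle one window's signals, events and cycles
#'
#' @param ax,ay,az Earth-frame component series (equal length).
#' @param fs sampling rate, Hz.
#' @param events a `gait_events` for the window (indices relative to it).
#' @param cycles cycle data frame from [segment_cycles()].
#' @return a `window_signals` object; `magnitude` is computed from the
#'   components.
#' @export
window_signals <- function(ax, ay, az, fs, events = NULL, cycles = NULL) {
  stopifnot(length(ax) == length(ay), length(ay) == length(az))
  if (is.null(events)) events <- gait_events(fs = fs)
  if (is.null(cycles)) cycles <- segment_cycles(events)
  structure(list(magnitude = sqrt(ax^2 + ay^2 + az^2),
                 ax = ax, ay = ay, az = az, fs = fs,
                 events = events, cycles = cycles),
            class = "window_signals")
}

#' Basic statistics of the four window signals
#'
#' Maximum, minimum, mean, median and sample standard deviation (denominator
#' N-1) of the magnitude and each component, in that stat-major order.
#'
#' @param w a `window_signals`.
#' @return named numeric vector of 20 values.
#' @export
basic_stats <- function(w) {
  sig <- list(mag = w$magnitude, ax = w$ax, ay = w$ay, az = w$az)
  stats_fun <- list(max = max, min = min, mean = mean,
                    median = stats::median, std = stats::sd)
  out <- unlist(lapply(names(stats_fun), function(s)
    vapply(sig, stats_fun[[s]], numeric(1))))
  names(out) <- as.vector(t(outer(names(stats_fun), SIGNAL_NAMES, paste, sep = "_")))
  out
}

#' Ten-bin distribution histogram
#'
#' Equal-width bins spanning the window's own min/max, normalized to
#' frequencies (sum 1). A zero-range series puts all mass in bin 1.
#'
#' @param series numeric series.
#' @return numeric vector of 10 frequencies.
#' @export
histogram10 <- function(series) {
  n <- length(series)
  if (n == 0) stop("empty series")
  rng <- range(series)
  if (diff(rng) == 0) return(c(1, rep(0, 9)))
  breaks <- seq(rng[1], rng[2], length.out = 11)
  counts <- graphics::hist(series, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  counts / n
}

#' Per-axis RMS ratios
#'
#' RMS of each axis over the total RMS across the three axes; the squared
#' ratios sum to 1 by construction.
#'
#' @param w a `window_signals`.
#' @return named numeric `c(rmsr_ax, rmsr_ay, rmsr_az)`; all `NA` when the
#'   total RMS is zero.
#' @export
rmsr <- function(w) {
  rms <- function(x) sqrt(mean(x^2))
  r <- c(rms(w$ax), rms(w$ay), rms(w$az))
  tot <- sqrt(sum(r^2))
  out <- if (tot == 0) rep(NA_real_, 3) else r / tot
  names(out) <- paste0("rmsr_", c("ax", "ay", "az"))
  out
}

#' Signal magnitude area
#'
#' Mean over samples of the summed absolute per-axis accelerations.
#'
#' @param w a `window_signals`.
#' @return scalar SMA, m/s^2.
#' @export
sma <- function(w) {
  mean(abs(w$ax) + abs(w$ay) + abs(w$az))
}

#' Moment kurtosis (non-excess)
#'
#' `N * sum(d^4) / (sum(d^2))^2` with `d = x - mean(x)`, i.e. m4/m2^2; 3 for
#' a normal population.
#'
#' @param series numeric series.
#' @return scalar kurtosis; `NA` for zero variance.
#' @export
moment_kurtosis <- function(series) {
  d <- series - mean(series)
  s2 <- sum(d^2)
  if (s2 == 0) return(NA_real_)
  length(series) * sum(d^4) / s2^2
}

#' Moment skewness
#'
#' `g = m3 / m2^(3/2)` with central moments `m_i = mean((x - mean(x))^i)`.
#'
#' @param series numeric series.
#' @return scalar skewness; `NA` for zero variance.
#' @export
moment_skewness <- function(series) {
  d <- series - mean(series)
  m2 <- mean(d^2)
  if (m2 == 0) return(NA_real_)
  mean(d^3) / m2^1.5
}

#' LCSS similarity between consecutive gait cycles
#'
#' Longest common subsequence with an amplitude threshold `eps` (two samples
#' match if their absolute difference is at most `eps`) and a temporal band
#' `delta` (index offset at most `delta`), normalized by the shorter cycle's
#' length and averaged over consecutive cycle pairs. Defaults: `eps` is half
#' the standard deviation of the window's magnitude, `delta` 10% of the
#' shorter cycle.
#'
#' @param cycle_series list of numeric series, one magnitude segment per
#'   cycle.
#' @param eps amplitude matching threshold; `NULL` for the default.
#' @param delta temporal band in samples; `NULL` for the default.
#' @return mean normalized LCSS in [0, 1]; `NA` with fewer than 2 cycles.
#' @export
lcss_similarity <- function(cycle_series, eps = NULL, delta = NULL) {
  if (length(cycle_series) < 2) return(NA_real_)
  if (is.null(eps)) eps <- 0.5 * stats::sd(unlist(cycle_series))
  sims <- vapply(seq_len(length(cycle_series) - 1), function(i) {
    a <- cycle_series[[i]]; b <- cycle_series[[i + 1]]
    d <- if (is.null(delta)) max(1L, round(0.1 * min(length(a), length(b)))) else delta
    lcss_length(a, b, eps, d) / min(length(a), length(b))
  }, numeric(1))
  mean(sims)
}

# Banded LCSS dynamic program; the answer is the best cell anywhere since
# cells outside the band are never computed.
lcss_length <- function(a, b, eps, delta) {
  na <- length(a); nb <- length(b)
  D <- matrix(0L, na + 1, nb + 1)
  best <- 0L
  for (i in seq_len(na)) {
    jlo <- max(1L, i - delta); jhi <- min(nb, i + delta)
    if (jlo > jhi) next
    for (j in jlo:jhi) {
      D[i + 1, j + 1] <- if (abs(a[i] - b[j]) <= eps)
        D[i, j] + 1L
      else max(D[i, j + 1], D[i + 1, j])
      if (D[i + 1, j + 1] > best) best <- D[i + 1, j + 1]
    }
  }
  best
}

#' Cadence in steps per minute
#'
#' @param events a `gait_events`.
#' @param duration window duration, seconds.
#' @return steps/min (total heel contacts per minute).
#' @export
cadence <- function(events, duration) {
  stopifnot(duration > 0)
  (length(events$rhc) + length(events$lhc)) / duration * 60
}

#' Mean stride time over a window's cycles
#'
#' @param cycles cycle data frame from [segment_cycles()].
#' @return mean stride time in seconds; `NA` with no cycles.
#' @export
mean_stride_time <- function(cycles) {
  if (nrow(cycles) == 0) return(NA_real_)
  mean(cycles$stride_time)
}

#' Swing/stance ratio of the gait cycle
#'
#' Mean over cycles of the stance percentage of the stride
#' (100 * stance/stride); about 60% in typical gait. `mode = "difference"`
#' instead returns the swing-minus-stance percentage-point difference.
#'
#' @param cycles cycle data frame from [segment_cycles()].
#' @param mode `"stance_percent"` (default) or `"difference"`.
#' @return percentage; `NA` when no cycle has a detected toe-off.
#' @export
swing_stance_ratio <- function(cycles, mode = c("stance_percent", "difference")) {
  mode <- match.arg(mode)
  ok <- !is.na(cycles$stance_time)
  if (!any(ok)) return(NA_real_)
  stance_pct <- 100 * cycles$stance_time[ok] / cycles$stride_time[ok]
  if (mode == "stance_percent") mean(stance_pct)
  else mean((100 - stance_pct) - stance_pct)
}

#' Compute the full 70-value time-domain block
#'
#' @param w a `window_signals`.
#' @return named numeric vector of exactly 70 values in schema order.
#' @export
time_features <- function(w) {
  stopifnot(inherits(w, "window_signals"))
  sig <- list(mag = w$magnitude, ax = w$ax, ay = w$ay, az = w$az)
  hist_block <- unlist(lapply(SIGNAL_NAMES, function(s) {
    v <- histogram10(sig[[s]])
    names(v) <- sprintf("hist%02d_%s", 1:10, s)
    v
  }))
  cyc_series <- cycle_magnitude_segments(w)
  out <- c(
    basic_stats(w),
    hist_block,
    rmsr(w),
    sma = sma(w),
    kurtosis_mag = moment_kurtosis(w$magnitude),
    skewness_mag = moment_skewness(w$magnitude),
    similarity_mag = lcss_similarity(cyc_series),
    cadence_ay = cadence(w$events, length(w$ay) / w$fs),
    stride_time_ay = mean_stride_time(w$cycles),
    swing_stance_ay = swing_stance_ratio(w$cycles)
  )
  stopifnot(length(out) == 70)
  out
}

# Magnitude segments of complete cycles (RHC to next RHC).
cycle_magnitude_segments <- function(w) {
  if (nrow(w$cycles) == 0) return(list())
  lapply(seq_len(nrow(w$cycles)), function(i)
    w$magnitude[w$cycles$start[i]:w$cycles$end[i]])
}
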