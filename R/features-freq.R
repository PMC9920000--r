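#' Frequency-domain gait features (85 per window)
#'
#' All frequency features are computed on the acceleration magnitude of a
#' 10 s window: Welch PSD summaries (max, mean, min), normalized spectral
#' entropy, spectral energy, 40 FFT magnitudes and 40 DCT coefficients
#' covering 0.1-4.0 Hz at 0.1 Hz resolution. The series mean is removed
#' before every transform so the excluded-DC convention is exact; gravity
#' handling happens upstream.
#'
#' @name features_freq
NULL

#' Welch power spectral density summaries
#'
#' Hann-windowed 128-sample segments with 50% overlap, averaged one-sided
#' periodograms (density scaling). Falls back to a single periodogram with a
#' warning when the series is shorter than one segment.
#'
#' @param mag acceleration-magnitude series.
#' @param fs sampling rate, Hz.
#' @param segment segment length, samples.
#' @return named numeric `c(psd_max, psd_mean, psd_min)`.
#' @export
psd_welch <- function(mag, fs, segment = 128) {
  x <- mag - mean(mag)
  n <- length(x)
  if (n < segment) {
    warning("series shorter than one Welch segment; single periodogram")
    segment <- n
  }
  step <- max(1, segment %/% 2)
  starts <- seq(1, n - segment + 1, by = step)
  win <- hann_window(segment)
  scale <- fs * sum(win^2)
  nb <- segment %/% 2 + 1
  psd <- rowMeans(vapply(starts, function(s) {
    seg <- x[s:(s + segment - 1)] * win
    p <- Mod(stats::fft(seg))[1:nb]^2 / scale
    # one-sided: double interior bins
    if (segment %% 2 == 0) p[2:(nb - 1)] <- 2 * p[2:(nb - 1)]
    else p[2:nb] <- 2 * p[2:nb]
    p
  }, numeric(nb)))
  c(psd_max = max(psd), psd_mean = mean(psd), psd_min = min(psd))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)

#' Normalized spectral entropy
#'
#' Shannon entropy of the FFT magnitude distribution over positive-frequency
#' non-DC bins, normalized by log(number of bins) to [0, 1].
#'
#' @param mag acceleration-magnitude series.
#' @return entropy in [0, 1]; `NA` when all non-DC bins are zero.
#' @export
spectral_entropy <- function(mag) {
  x <- mag - mean(mag)
  n <- length(x)
  a <- Mod(stats::fft(x))[2:(n %/% 2 + 1)]
  tot <- sum(a)
  if (tot == 0) return(NA_real_)
  p <- a / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(a))
}

#' Spectral energy
#'
#' Squared sum of the (two-sided) FFT coefficients normalized by the window
#' length; by Parseval this equals the sum of squares of the demeaned
#' series.
#'
#' @param mag acceleration-magnitude series.
#' @return spectral energy.
#' @export
spectral_energy <- function(mag) {
  x <- mag - mean(mag)
  sum(Mod(stats::fft(x))^2) / length(x)
}

#' FFT coefficients over 0.1-4.0 Hz
#'
#' Magnitudes of FFT bins 1..40 scaled by 2/N. A 10 s window at 50 Hz (500
#' samples) puts the bin spacing at exactly 0.1 Hz, so the 40 bins span
#' 0.1-4.0 Hz.
#'
#' @param mag acceleration-magnitude series (length `fs * 10`).
#' @param fs sampling rate, Hz.
#' @return named numeric vector `fft_01` .. `fft_40`.
#' @export
fft_coefficients <- function(mag, fs = 50) {
  n <- length(mag)
  if (n != fs * 10)
    stop("window must be exactly 10 s (", fs * 10, " samples at ", fs, " Hz)")
  x <- mag - mean(mag)
  a <- 2 / n * Mod(stats::fft(x))[2:41]
  names(a) <- sprintf("fft_%02d", 1:40)
  a
}

#' DCT coefficients over 0.1-4.0 Hz
#'
#' Orthonormal type-II DCT of the demeaned window. DCT bin k corresponds to
#' frequency k * fs / (2N), i.e. 0.05 Hz per bin at N = 500, so the even
#' bins k = 2, 4, ..., 80 give the stated 0.1 Hz resolution up to 4.0 Hz.
#' `bins = "first40"` instead returns bins 1..40.
#'
#' @param mag acceleration-magnitude series (length `fs * 10`).
#' @param fs sampling rate, Hz.
#' @param bins `"even"` (default, 0.1 Hz spacing) or `"first40"`.
#' @return named numeric vector `dct_01` .. `dct_40` (signed).
#' @export
dct_coefficients <- function(mag, fs = 50, bins = c("even", "first40")) {
  bins <- match.arg(bins)
  n <- length(mag)
  if (n != fs * 10)
    stop("window must be exactly 10 s (", fs * 10, " samples at ", fs, " Hz)")
  x <- mag - mean(mag)
  k <- if (bins == "even") seq(2, 80, by = 2) else 1:40
  d <- dct2_ortho(x, k)
  names(d) <- sprintf("dct_%02d", 1:40)
  d
}

# Orthonormal DCT-II coefficients of x at indices k (k = 0 is the DC term).
dct2_ortho <- function(x, k) {
  n <- length(x)
  m <- seq_len(n) - 1
  vapply(k, function(kk) {
    s <- if (kk == 0) sqrt(1 / n) else sqrt(2 / n)
    s * sum(x * cos(pi * (2 * m + 1) * kk / (2 * n)))
  }, numeric(1))
}

#' Compute the full 85-value frequency-domain block
#'
#' @param w a `window_signals`.
#' @return named numeric vector of exactly 85 values in schema order.
#' @export
freq_features <- function(w) {
  stopifnot(inherits(w, "window_signals"))
  mag <- w$magnitude
  out <- c(
    psd_welch(mag, w$fs),
    entropy = spectral_entropy(mag),
    spectral_energy = spectral_energy(mag),
    fft_coefficients(mag, w$fs),
    dct_coefficients(mag, w$fs)
  )
  stopifnot(length(out) == 85)
  out
}

#' Full per-window feature vector (155 values)
#'
#' Concatenates the time-domain and frequency-domain blocks.
#'
#' @param w a `window_signals`.
#' @return named numeric vector of exactly 155 values.
#' @export
window_features <- function(w) {
  c(time_features(w), freq_features(w))
}

#' Machine-readable feature schema
#'
#' @return data frame with `index`, `name`, `domain` for all 155 features,
#'   in dataset column order.
#' @export
feature_schema <- function() {
  w <- template_window()
  nm <- names(window_features(w))
  data.frame(index = seq_along(nm), name = nm,
             domain = rep(c("time", "frequency"), c(70, 85)))
}

# Minimal deterministic window used to derive the schema.
template_window <- function() {
  fs <- 50
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  ev <- gait_events(rhc = c(1L, 56L, 111L), lhc = c(28L, 83L),
                    rto = c(34L, 89L), lto = c(6L, 61L), fs = fs)
  window_signals(ax = 0.3 * sin(2 * pi * 0.9 * t),
                 ay = 3 * sin(2 * pi * 1.8 * t),
                 az = sin(2 * pi * 0.9 * t + 1), fs = fs, events = ev)
}
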