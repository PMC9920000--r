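#' Singular spectrum analysis
#'
#' SSA embeds a series into a Hankel trajectory matrix, takes its SVD, and
#' reconstructs one additive component per singular triple by diagonal
#' averaging. Components separate trend, oscillations and noise; here they
#' isolate the stride-periodic oscillation of the vertical acceleration that
#' drives gait-event detection.
#'
#' Each elementary matrix is rank one, so diagonal averaging reduces to the
#' full linear convolution of its singular vectors divided by the
#' anti-diagonal lengths; the decomposition is exact (components sum to the
#' input).
#'
#' @name ssa
NULL

#' Decompose a series by SSA
#'
#' @param signal uniform numeric series.
#' @param L embedding (window) length in samples, 2 <= L <= length/2.
#' @return an `ssa_decomposition`: list with `embedding_length`,
#'   `eigenvalues` (squared singular values, descending), `components`
#'   (matrix, one reconstructed component per column, same length as input).
#' @export
ssa_decompose <- function(signal, L) {
  n <- length(signal)
  if (L < 2 || L > n / 2) stop("L must satisfy 2 <= L <= length(signal)/2")
  K <- n - L + 1
  X <- stats::embed(signal, L)[, L:1, drop = FALSE]   # K x L, rows are lags
  s <- svd(t(X))                                      # L x K trajectory matrix
  counts <- stats::convolve(rep(1, L), rev(rep(1, K)), type = "open")
  r <- sum(s$d > max(s$d[1], 0) * 1e-12)
  comps <- vapply(seq_len(max(r, 1L)), function(i) {
    s$d[i] * stats::convolve(s$u[, i], rev(s$v[, i]), type = "open") / counts
  }, numeric(n))
  structure(list(
    embedding_length = L,
    eigenvalues = s$d^2,
    components = comps,
    signal = signal
  ), class = "ssa_decomposition")
}

#' @export
print.ssa_decomposition <- function(x, ...) {
  ev <- x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("<ssa_decomposition> L = %d, %d components (top shares %s)\n",
              x$embedding_length, ncol(x$components),
              paste(sprintf("%.2f", utils::head(ev, 3)), collapse = ", ")))
  invisible(x)
}

# Dominant periodogram frequency of a series, Hz (DC bin included).
dominant_frequency <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))[1:(n %/% 2 + 1)]^2
  (which.max(p) - 1) * fs / n
}

#' Split an SSA decomposition into trend and detrended series
#'
#' The trend is the group of components whose dominant periodogram frequency
#' is below `trend_max_hz`; the detrended series is the input minus the
#' trend. An empty trend group is allowed.
#'
#' @param decomp an `ssa_decomposition`.
#' @param fs sampling rate, Hz.
#' @param trend_max_hz frequency below which a component counts as trend.
#' @return list with `detrended` and `trend` series.
#' @export
remove_trend <- function(decomp, fs, trend_max_hz = 0.5) {
  stopifnot(inherits(decomp, "ssa_decomposition"))
  f <- apply(decomp$components, 2, dominant_frequency, fs = fs)
  is_trend <- f < trend_max_hz
  trend <- if (any(is_trend))
    rowSums(decomp$components[, is_trend, drop = FALSE])
  else rep(0, length(decomp$signal))
  list(detrended = decomp$signal - trend, trend = trend)
}

#' Reconstruct the dominant oscillation of a detrended series
#'
#' Reconstructs from the leading eigenvalue group. A harmonic contributes a
#' near-degenerate pair of singular triples, so components whose singular
#' value is within `pair_tol` of the largest are grouped with it; this
#' recovers the stride-periodic oscillation in amplitude and phase.
#'
#' @param detrended detrended series.
#' @param L embedding length in samples.
#' @param pair_tol relative singular-value tolerance for grouping with the
#'   leading component.
#' @return the dominant-oscillation series (same length as input).
#' @export
dominant_oscillation <- function(detrended, L, pair_tol = 0.2) {
  d <- ssa_decompose(detrended, L)
  sv <- sqrt(d$eigenvalues[seq_len(ncol(d$components))])
  keep <- sv >= (1 - pair_tol) * sv[1]
  # only the leading contiguous run: stop at the first excluded component
  stop_at <- which(!keep)[1]
  if (!is.na(stop_at)) keep[stop_at:length(keep)] <- FALSE
  rowSums(d$components[, keep, drop = FALSE])
}
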