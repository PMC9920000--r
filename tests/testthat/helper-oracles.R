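# Independent brute-force oracles for the feature definitions. Deliberately
# naive (explicit loops / direct sums) and kept separate from the package
# implementation.

oracle_std <- function(x) {
  m <- sum(x) / length(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (length(x) - 1))
}

oracle_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v^2
  sqrt(s / length(x))
}

oracle_rmsr <- function(ax, ay, az) {
  r <- c(oracle_rms(ax), oracle_rms(ay), oracle_rms(az))
  r / sqrt(r[1]^2 + r[2]^2 + r[3]^2)
}

oracle_sma <- function(ax, ay, az) {
  s <- 0
  for (i in seq_along(ax)) s <- s + abs(ax[i]) + abs(ay[i]) + abs(az[i])
  s / length(ax)
}

oracle_kurtosis <- function(x) {
  m <- mean(x); d4 <- 0; d2 <- 0
  for (v in x) { d4 <- d4 + (v - m)^4; d2 <- d2 + (v - m)^2 }
  length(x) * d4 / d2^2
}

oracle_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  m3 / m2^1.5
}

# Welch PSD via an explicit DFT matrix (no fft), Hann window, 50% overlap.
oracle_welch <- function(x, fs, segment = 128) {
  x <- x - mean(x)
  n <- length(x)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(segment) / segment)
  k <- 0:(segment %/% 2)
  W <- exp(-2i * pi * outer(k, 0:(segment - 1)) / segment)
  starts <- seq(1, n - segment + 1, by = segment %/% 2)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + segment - 1)] * win
    p <- Mod(W %*% seg)^2 / (fs * sum(win^2))
    p[2:(length(k) - 1)] <- 2 * p[2:(length(k) - 1)]
    acc <- acc + p
  }
  drop(acc) / length(starts)
}

# Exponential-time recursive LCSS with the same amplitude/temporal band.
oracle_lcss <- function(a, b, eps, delta) {
  rec <- function(i, j) {
    if (i == 0 || j == 0) return(0L)
    if (abs(i - j) <= delta && abs(a[i] - b[j]) <= eps)
      return(rec(i - 1, j - 1) + 1L)
    max(rec(i - 1, j), rec(i, j - 1))
  }
  rec(length(a), length(b))
}
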