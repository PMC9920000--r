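#' Gait-event detection from Earth-frame acceleration
#'
#' Heel contacts and toe-offs are located on the SSA-detrended vertical (Y)
#' and anterior-posterior (Z) acceleration. The stride-periodic dominant
#' oscillation of Y provides candidate minima; each candidate is refined to
#' the minimum of the product of the detrended Y and Z signals inside a short
#' interval; the left/right side is decided once from the mean amplitude of
#' the detrended Y between the first three dominant-oscillation minima and
#' propagated alternately. Toe-offs are extrema of the detrended Y between
#' labeled heel contacts. Labels are phone-side-relative: the pocket side
#' produces the larger ipsilateral peak, and the pocket side is unknown, so
#' "right" means "the side with the larger post-contact amplitude".
#'
#' @name gait_events
NULL

#' Local extrema by order-based comparison
#'
#' Index `i` is a local minimum (maximum) if it is strictly the smallest
#' (largest) among samples within `order` positions, suppressing micro-extrema
#' closer than `order` samples.
#'
#' @param x numeric series.
#' @param order neighborhood half-width, samples.
#' @param what `"min"` or `"max"`.
#' @return integer indices of the extrema.
#' @export
local_extrema <- function(x, order = 1, what = c("min", "max")) {
  what <- match.arg(what)
  if (what == "max") x <- -x
  n <- length(x)
  if (n < 3) return(integer(0))
  order <- max(1L, as.integer(order))
  cand <- which(vapply(2:(n - 1), function(i) {
    lo <- max(1, i - order); hi <- min(n, i + order)
    x[i] == min(x[lo:hi]) && sum(x[lo:hi] == x[i]) == 1
  }, logical(1))) + 1L
  cand
}

#' Construct a gait-event set
#'
#' @param rhc,lhc,rto,lto strictly increasing sample indices of right/left
#'   heel contacts and toe-offs.
#' @param fs sampling rate, Hz.
#' @return a `gait_events` object.
#' @export
gait_events <- function(rhc = integer(0), lhc = integer(0),
                        rto = integer(0), lto = integer(0), fs) {
  for (v in list(rhc, lhc, rto, lto))
    if (is.unsorted(v, strictly = TRUE)) stop("event indices must be strictly increasing")
  structure(list(rhc = as.integer(rhc), lhc = as.integer(lhc),
                 rto = as.integer(rto), lto = as.integer(lto), fs = fs),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d RHC, %d LHC, %d RTO, %d LTO at %g Hz\n",
              length(x$rhc), length(x$lhc), length(x$rto), length(x$lto), x$fs))
  invisible(x)
}

#' Detect candidate heel contacts
#'
#' Minima of the dominant Y oscillation give one candidate interval per step;
#' within each interval (half-width 25% of the median inter-minimum spacing)
#' the index minimizing `y_rec * z_rec` is the heel contact.
#'
#' @param y_dom dominant oscillation of the detrended vertical acceleration.
#' @param y_rec,z_rec detrended vertical and anterior-posterior series.
#' @param fs sampling rate, Hz.
#' @return list with `contacts` (refined indices) and `minima` (the dominant
#'   oscillation minima the contacts derive from); both empty when fewer than
#'   3 minima are found.
#' @export
detect_heel_contacts <- function(y_dom, y_rec, z_rec, fs) {
  stopifnot(length(y_dom) == length(y_rec), length(y_rec) == length(z_rec))
  step_hz <- dominant_frequency(y_dom - mean(y_dom), fs)
  ord <- if (step_hz > 0) max(2L, round(0.25 * fs / step_hz)) else 2L
  minima <- local_extrema(y_dom, order = ord, what = "min")
  if (length(minima) < 3)
    return(list(contacts = integer(0), minima = integer(0)))
  half <- max(1L, round(0.25 * stats::median(diff(minima))))
  prod_yz <- y_rec * z_rec
  contacts <- vapply(minima, function(m) {
    lo <- max(1L, m - half); hi <- min(length(prod_yz), m + half)
    as.integer(lo + which.min(prod_yz[lo:hi]) - 1L)
  }, integer(1))
  contacts <- sort(unique(contacts))
  list(contacts = contacts, minima = minima)
}

#' Assign left/right side to heel contacts
#'
#' Parity is decided once from the first three dominant-oscillation minima:
#' if the mean of the detrended Y between minima 1 and 2 exceeds the mean
#' between minima 2 and 3, the first contact is an RHC; labels then alternate.
#' Ties default to first-contact-is-RHC with a warning.
#'
#' @param contacts refined heel-contact indices.
#' @param y_rec detrended vertical series.
#' @param y_dom_minima dominant-oscillation minima (used for the segments).
#' @return list with `rhc` and `lhc` index vectors.
#' @export
assign_left_right <- function(contacts, y_rec, y_dom_minima) {
  if (length(contacts) < 3 || length(y_dom_minima) < 3)
    stop("need at least 3 contacts to assign sides")
  m <- y_dom_minima[1:3]
  mean12 <- mean(y_rec[m[1]:m[2]])
  mean23 <- mean(y_rec[m[2]:m[3]])
  if (abs(mean12 - mean23) < 1e-9) {
    warning("tie in inter-minimum means; defaulting to first contact = RHC")
    first_is_rhc <- TRUE
  } else first_is_rhc <- mean12 > mean23
  idx <- seq_along(contacts)
  odd <- idx %% 2 == 1
  if (first_is_rhc) list(rhc = contacts[odd], lhc = contacts[!odd])
  else list(rhc = contacts[!odd], lhc = contacts[odd])
}

#' Detect toe-offs from labeled heel contacts
#'
#' For each LHC, the RTO is the first local minimum of the detrended Y
#' strictly after the LHC and before the next RHC; the LTO is the last local
#' maximum strictly before the LHC and after the preceding RHC. Cycles with
#' no qualifying extremum carry no toe-off.
#'
#' @param rhc,lhc labeled heel-contact indices.
#' @param y_rec detrended vertical series.
#' @param order extrema neighborhood half-width, samples.
#' @return list with `rto` and `lto` index vectors.
#' @export
detect_toe_offs <- function(rhc, lhc, y_rec, order = 2) {
  mins <- local_extrema(y_rec, order = order, what = "min")
  maxs <- local_extrema(y_rec, order = order, what = "max")
  rto <- integer(0); lto <- integer(0)
  for (l in lhc) {
    next_rhc <- rhc[rhc > l][1]
    prev_rhc <- rev(rhc[rhc < l])[1]
    if (!is.na(next_rhc)) {
      cand <- mins[mins > l & mins < next_rhc]
      if (length(cand)) rto <- c(rto, cand[1])
    }
    if (!is.na(prev_rhc)) {
      cand <- maxs[maxs < l & maxs > prev_rhc]
      if (length(cand)) lto <- c(lto, cand[length(cand)])
    }
  }
  list(rto = sort(unique(rto)), lto = sort(unique(lto)))
}

#' Run the full gait-event detector on one Y/Z segment
#'
#' Convenience wrapper: SSA detrend both axes, reconstruct the dominant Y
#' oscillation, then detect and label heel contacts and toe-offs.
#'
#' @param y,z Earth-frame vertical and anterior-posterior acceleration.
#' @param fs sampling rate, Hz.
#' @param L SSA embedding length, samples (default 2 s worth).
#' @return a `gait_events` object (empty if the segment has no usable gait).
#' @export
detect_gait_events <- function(y, z, fs, L = round(2 * fs)) {
  n <- length(y)
  empty <- gait_events(fs = fs)
  if (n < 2 * L || stats::sd(y) == 0) return(empty)
  dy <- remove_trend(ssa_decompose(y, L), fs)
  dz <- remove_trend(ssa_decompose(z, L), fs)
  if (stats::sd(dy$detrended) == 0) return(empty)
  y_dom <- dominant_oscillation(dy$detrended, L)
  hc <- detect_heel_contacts(y_dom, dy$detrended, dz$detrended, fs)
  if (length(hc$contacts) < 3) return(empty)
  side <- assign_left_right(hc$contacts, dy$detrended, hc$minima)
  to <- detect_toe_offs(side$rhc, side$lhc, dy$detrended)
  gait_events(rhc = side$rhc, lhc = side$lhc, rto = to$rto, lto = to$lto,
              fs = fs)
}

#' Segment gait cycles between consecutive RHC events
#'
#' One cycle per consecutive RHC pair. Stride time is the RHC-to-RHC
#' interval; stance is RHC to the RTO inside the cycle; swing is the
#' remainder. Cycles missing interior events keep their stride time with
#' `NA` stance/swing.
#'
#' @param events a `gait_events` object.
#' @return data frame with one row per cycle: `start`, `end`, `stride_time`,
#'   `stance_time`, `swing_time`, `lto`, `lhc`, `rto`.
#' @export
segment_cycles <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  r <- events$rhc
  if (length(r) < 2)
    return(data.frame(start = integer(0), end = integer(0),
                      stride_time = numeric(0), stance_time = numeric(0),
                      swing_time = numeric(0), lto = integer(0),
                      lhc = integer(0), rto = integer(0)))
  fs <- events$fs
  one <- function(a, b) {
    inside <- function(v) { x <- v[v > a & v < b]; if (length(x)) x[1] else NA_integer_ }
    lto <- inside(events$lto); lhc <- inside(events$lhc); rto <- inside(events$rto)
    stance <- if (!is.na(rto)) (rto - a) / fs else NA_real_
    stride <- (b - a) / fs
    data.frame(start = a, end = b, stride_time = stride,
               stance_time = stance, swing_time = stride - stance,
               lto = lto, lhc = lhc, rto = rto)
  }
  do.call(rbind, Map(one, r[-length(r)], r[-1]))
}
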