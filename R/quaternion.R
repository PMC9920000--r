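#' Quaternion utilities
#'
#' Minimal scalar-first unit-quaternion algebra used by the orientation
#' estimator and the gait simulator. A quaternion is a numeric vector
#' `c(w, x, y, z)`; a quaternion series is an `n x 4` matrix with one
#' quaternion per row. All rotations are body-to-Earth: `quat_rotate(q, v)`
#' expresses the body-frame vector `v` in the Earth-fixed frame.
#'
#' @param q,p numeric length-4 quaternions, scalar first.
#' @name quaternion
NULL

#' @rdname quaternion
#' @export
quat_multiply <- function(q, p) {
  c(q[1] * p[1] - q[2] * p[2] - q[3] * p[3] - q[4] * p[4],
    q[1] * p[2] + q[2] * p[1] + q[3] * p[4] - q[4] * p[3],
    q[1] * p[3] - q[2] * p[4] + q[3] * p[1] + q[4] * p[2],
    q[1] * p[4] + q[2] * p[3] - q[3] * p[2] + q[4] * p[1])
}

#' @rdname quaternion
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' @rdname quaternion
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Rotation matrix of a unit quaternion (body-to-Earth)
#' @param q unit quaternion, scalar first.
#' @return 3 x 3 orthogonal matrix `R` with `v_earth = R %*% v_body`.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' @rdname quaternion
#' @param v numeric length-3 vector in the body frame.
#' @export
quat_rotate <- function(q, v) {
  # v + 2 r x (r x v + w v), r = vector part; body -> Earth
  r <- q[2:4]
  t1 <- cross3(r, v) + q[1] * v
  v + 2 * cross3(r, t1)
}

#' @rdname quaternion
#' @param axis numeric length-3 rotation axis (need not be unit).
#' @param angle rotation angle in radians.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) return(c(1, 0, 0, 0))
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Logarithm map: rotation vector (axis * angle, radians) of a unit quaternion.
quat_log_vec <- function(q) {
  if (q[1] < 0) q <- -q             # shortest arc
  vn <- sqrt(sum(q[2:4]^2))
  if (vn < 1e-12) return(c(0, 0, 0))
  angle <- 2 * atan2(vn, q[1])
  q[2:4] / vn * angle
}

# Spherical linear interpolation between unit quaternions, t in [0, 1].
quat_slerp <- function(q0, q1, t) {
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }
  if (d > 1 - 1e-10) return(quat_normalize((1 - t) * q0 + t * q1))
  th <- acos(pmin(1, d))
  (sin((1 - t) * th) * q0 + sin(t * th) * q1) / sin(th)
}
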