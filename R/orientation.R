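#' Phone orientation estimation and Earth-frame rotation
#'
#' The phone rides free-oriented in a trouser pocket, so body-frame
#' acceleration is meaningless across trials. Orientation is estimated per
#' sample by Madgwick gradient-descent fusion of gyroscope, accelerometer and
#' magnetometer, and acceleration is rotated into an Earth-fixed frame with
#' axes X = medio-lateral, Y = vertical (up), Z = anterior-posterior
#' (magnetic north). Euler angles follow the phone convention: roll about Z,
#' pitch about X, yaw (heading) about Y, applied as R = Ry(yaw) Rx(pitch)
#' Rz(roll).
#'
#' @name orientation
NULL

GRAVITY_MS2 <- 9.8

#' One Madgwick MARG filter update
#'
#' Gradient-descent-corrected gyroscope integration: the quaternion rate from
#' the gyro is corrected along the normalized gradient of the combined
#' gravity + magnetic-field alignment objective, scaled by `beta` (rad/s).
#' A zero-norm accelerometer or magnetometer sample disables the correction
#' for that step (gyro-only integration); `mag = NULL` selects the IMU-only
#' variant (gravity correction only, yaw unreferenced).
#'
#' @param q current unit quaternion (body-to-Earth, scalar first).
#' @param gyro angular rate, rad/s, body frame (length 3).
#' @param accel specific force, m/s^2, body frame (length 3).
#' @param mag magnetic field, uT, body frame (length 3), or `NULL`.
#' @param dt time step, seconds.
#' @param beta filter gain, rad/s.
#' @return updated unit quaternion.
#' @export
madgwick_step <- function(q, gyro, accel, mag, dt, beta = 0.1) {
  stopifnot(dt > 0, length(q) == 4)
  qdot <- 0.5 * quat_multiply(q, c(0, gyro))

  an <- sqrt(sum(accel^2))
  use_acc <- an > 0
  use_mag <- !is.null(mag) && sqrt(sum(mag^2)) > 0
  if (use_acc) {
    a <- accel / an
    f <- body_ref(q, c(0, 1, 0)) - a
    J <- body_ref_jacobian(q, c(0, 1, 0))
    grad <- drop(t(J) %*% f)
    if (use_mag) {
      m <- mag / sqrt(sum(mag^2))
      h <- quat_rotate(q, m)                       # field in Earth frame
      b <- c(0, h[2], sqrt(h[1]^2 + h[3]^2))       # north along +Z, dip on Y
      fm <- body_ref(q, b) - m
      Jm <- body_ref_jacobian(q, b)
      grad <- grad + drop(t(Jm) %*% fm)
    }
    gn <- sqrt(sum(grad^2))
    if (gn > 0) qdot <- qdot - beta * grad / gn
  }
  quat_normalize(q + qdot * dt)
}

# Earth-frame reference direction d expressed in the body frame: R(q)^T d.
body_ref <- function(q, d) {
  quat_rotate(quat_conjugate(q), d)
}

# Analytic 3x4 Jacobian of body_ref(q, d) with respect to q = (w, x, y, z).
body_ref_jacobian <- function(q, d) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  d1 <- d[1]; d2 <- d[2]; d3 <- d[3]
  matrix(c(
    2 * (d2 * z - d3 * y), 2 * (d2 * y + d3 * z),
    -4 * d1 * y + 2 * d2 * x - 2 * d3 * w, -4 * d1 * z + 2 * d2 * w + 2 * d3 * x,
    2 * (-d1 * z + d3 * x), 2 * d1 * y - 4 * d2 * x + 2 * d3 * w,
    2 * (d1 * x + d3 * z), -2 * d1 * w - 4 * d2 * z + 2 * d3 * y,
    2 * (d1 * y - d2 * x), 2 * d1 * z - 2 * d2 * w - 4 * d3 * x,
    2 * d1 * w + 2 * d2 * z - 4 * d3 * y, 2 * (d1 * x + d2 * y)
  ), nrow = 3, byrow = TRUE)
}

#' Euler angles of a unit quaternion (phone convention)
#'
#' Decomposes the body-to-Earth rotation as R = Ry(yaw) Rx(pitch) Rz(roll):
#' roll about the phone Z-axis, pitch about X, yaw about the vertical Y.
#' Angles are returned in degrees, yaw and roll in (-180, 180]. Orientations
#' within 1 degree of gimbal lock (|pitch| > 89) are flagged via the
#' `"gimbal"` attribute.
#'
#' @param q unit quaternion, or an `n x 4` matrix of quaternions.
#' @return named numeric `c(roll, pitch, yaw)` in degrees, or an `n x 3`
#'   matrix with those columns.
#' @export
to_euler <- function(q) {
  if (is.matrix(q)) {
    out <- t(apply(q, 1, to_euler))
    colnames(out) <- c("roll", "pitch", "yaw")
    return(out)
  }
  R <- quat_to_matrix(q)
  pitch <- asin(max(-1, min(1, -R[2, 3])))
  roll <- atan2(R[2, 1], R[2, 2])
  yaw <- atan2(R[1, 3], R[3, 3])
  ang <- c(roll = roll, pitch = pitch, yaw = yaw) * 180 / pi
  if (abs(ang[["pitch"]]) > 89) attr(ang, "gimbal") <- TRUE
  ang
}

#' @rdname to_euler
#' @param roll,pitch,yaw angles in degrees.
#' @export
euler_to_quat <- function(roll, pitch, yaw) {
  d <- pi / 180
  qy <- quat_from_axis_angle(c(0, 1, 0), yaw * d)
  qx <- quat_from_axis_angle(c(1, 0, 0), pitch * d)
  qz <- quat_from_axis_angle(c(0, 0, 1), roll * d)
  quat_multiply(quat_multiply(qy, qx), qz)
}

#' Estimate per-sample orientation of a uniform IMU recording
#'
#' Runs the Madgwick filter over the recording. The filter is initialized
#' analytically from the first accelerometer/magnetometer sample (TRIAD-style
#' tilt + heading), and the first `warmup` seconds are flagged as the
#' convergence period; downstream gait analysis excludes them by default.
#' Without a magnetometer the IMU-only variant runs and yaw is unreferenced.
#'
#' @param rec a `uniform_imu_recording`.
#' @param beta Madgwick gain, rad/s.
#' @param warmup convergence period to flag, seconds.
#' @return an `orientation_series`: list with `quaternions` (n x 4), `euler`
#'   (n x 3, degrees), `fs`, `warmup_s`, `warmup_samples`, `yaw_referenced`.
#' @export
estimate_orientation <- function(rec, beta = 0.1, warmup = 5) {
  stopifnot(inherits(rec, "uniform_imu_recording"))
  n <- nrow(rec$accel)
  dt <- 1 / rec$rate
  has_mag <- !is.null(rec$mag) && !all(rec$mag == 0)
  q <- init_quaternion(rec$accel[1, ], if (has_mag) rec$mag[1, ] else NULL)
  Q <- matrix(NA_real_, n, 4)
  Q[1, ] <- q
  for (i in seq_len(n - 1)) {
    q <- madgwick_step(q, rec$gyro[i + 1, ], rec$accel[i + 1, ],
                       if (has_mag) rec$mag[i + 1, ] else NULL,
                       dt = dt, beta = beta)
    Q[i + 1, ] <- q
  }
  structure(list(
    quaternions = Q,
    euler = to_euler(Q),
    fs = rec$rate,
    warmup_s = warmup,
    warmup_samples = seq_len(min(n, round(warmup * rec$rate))),
    yaw_referenced = has_mag
  ), class = "orientation_series")
}

# Analytic initial attitude from one accelerometer (+ optional magnetometer)
# sample: body-frame coordinates of the Earth axes, assembled into R.
init_quaternion <- function(accel, mag = NULL) {
  an <- sqrt(sum(accel^2))
  if (an == 0) return(c(1, 0, 0, 0))
  up <- accel / an
  north <- NULL
  if (!is.null(mag) && sqrt(sum(mag^2)) > 0) {
    mh <- mag - sum(mag * up) * up
    if (sqrt(sum(mh^2)) > 1e-8) north <- mh / sqrt(sum(mh^2))
  }
  if (is.null(north)) {
    # tilt only: any horizontal direction serves as provisional north
    seed <- if (abs(up[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    north <- seed - sum(seed * up) * up
    north <- north / sqrt(sum(north^2))
  }
  east <- cross3(up, north)
  R <- rbind(east, up, north)        # rows: Earth X, Y, Z in body coords
  matrix_to_quat(R)
}

matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  quat_normalize(q)
}

#' Rotate body-frame acceleration into the Earth-fixed frame
#'
#' Applies each sample's quaternion to the body-frame acceleration. With
#' `remove_gravity` the constant (0, 9.8, 0) m/s^2 is subtracted after
#' rotation, leaving dynamic acceleration only.
#'
#' @param rec a `uniform_imu_recording`.
#' @param ori an `orientation_series` aligned sample-for-sample with `rec`.
#' @param remove_gravity subtract gravity after rotation?
#' @return an `earth_frame_recording`: list with `rate`, `accel_earth`
#'   (n x 3; X medio-lateral, Y vertical, Z anterior-posterior),
#'   `gravity_removed`, `warmup_samples`.
#' @export
rotate_to_earth <- function(rec, ori, remove_gravity = TRUE) {
  stopifnot(inherits(rec, "uniform_imu_recording"),
            inherits(ori, "orientation_series"))
  if (nrow(rec$accel) != nrow(ori$quaternions))
    stop("recording and orientation series have different lengths")
  ae <- rotate_rows(ori$quaternions, rec$accel)
  if (remove_gravity) ae[, 2] <- ae[, 2] - GRAVITY_MS2
  colnames(ae) <- c("x", "y", "z")
  structure(list(
    rate = rec$rate,
    accel_earth = ae,
    gravity_removed = remove_gravity,
    warmup_samples = ori$warmup_samples
  ), class = "earth_frame_recording")
}

# Vectorized body->Earth rotation of row-aligned vectors by row quaternions.
rotate_rows <- function(Q, V) {
  w <- Q[, 1]; r <- Q[, 2:4, drop = FALSE]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  t1 <- cr(r, V) + w * V
  V + 2 * cr(r, t1)
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series> %d samples at %g Hz, warmup %g s, yaw %s\n",
              nrow(x$quaternions), x$fs, x$warmup_s,
              if (x$yaw_referenced) "magnetically referenced" else "unreferenced"))
  invisible(x)
}

#' @export
print.earth_frame_recording <- function(x, ...) {
  cat(sprintf("<earth_frame_recording> %d samples at %g Hz, gravity %s\n",
              nrow(x$accel_earth), x$rate,
              if (x$gravity_removed) "removed" else "retained"))
  invisible(x)
}

#' Median of angles with wrap-around handling
#'
#' Ordinary medians of headings near +/-180 degrees are meaningless; this
#' recenters angles on their circular mean before taking the median.
#'
#' @param deg angles in degrees.
#' @return median angle in degrees, in (-180, 180].
#' @export
angle_median <- function(deg) {
  r <- deg * pi / 180
  ref <- atan2(mean(sin(r)), mean(cos(r)))
  dev <- ((r - ref + pi) %% (2 * pi)) - pi
  wrap_deg((ref + stats::median(dev)) * 180 / pi)
}

wrap_deg <- function(d) {
  w <- ((d + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}
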