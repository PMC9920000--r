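test_that("the Madgwick update has the consistent stationary fixed point", {
  q <- c(1, 0, 0, 0)
  for (i in 1:50)
    q <- madgwick_step(q, c(0, 0, 0), c(0, 9.8, 0),
                       claudigait:::MAG_EARTH_UT, dt = 0.02)
  expect_lt(sum(abs(q - c(1, 0, 0, 0))), 1e-6)
})

test_that("gyro-only integration matches closed-form quaternion integration", {
  q <- c(1, 0, 0, 0)
  omega <- 0.8; t_total <- 1.5; dt <- 0.005
  for (i in seq_len(t_total / dt))
    q <- madgwick_step(q, c(0, 0, omega), c(0, 0, 0), NULL, dt)
  expected <- quat_from_axis_angle(c(0, 0, 1), omega * t_total)
  expect_lt(2 * acos(min(1, abs(sum(q * expected)))), 1e-3)
})

test_that("noisy stationary input converges to the magnetic heading", {
  set.seed(11)
  true_q <- euler_to_quat(roll = 10, pitch = -15, yaw = 40)
  sim <- simulate_static_poses(list(true_q), 10, seed = 11)
  u <- filter_recording(resample_linear(sim$raw))
  ori <- estimate_orientation(u, beta = 0.1, warmup = 5)
  tail_idx <- seq(7 * 50, nrow(ori$euler))
  expect_lt(abs(angle_median(ori$euler[tail_idx, "yaw"]) - 40), 2)
})

test_that("quaternions stay unit-norm through updates", {
  set.seed(12)
  q <- quat_normalize(rnorm(4))
  for (i in 1:200) {
    q <- madgwick_step(q, rnorm(3), rnorm(3, c(0, 9, 0)), rnorm(3, c(5, -40, 20)),
                       dt = 0.02)
    expect_equal(sum(q^2), 1, tolerance = 1e-9)
  }
})

test_that("Euler angles follow the phone convention and round-trip", {
  expect_equal(unname(to_euler(c(1, 0, 0, 0))), c(0, 0, 0))
  yaw180 <- quat_from_axis_angle(c(0, 1, 0), pi)
  expect_equal(abs(to_euler(yaw180)[["yaw"]]), 180, tolerance = 1e-9)
  roll90 <- quat_from_axis_angle(c(0, 0, 1), pi / 2)
  expect_equal(to_euler(roll90)[["roll"]], 90, tolerance = 1e-9)

  set.seed(13)
  for (i in 1:20) {
    q <- quat_normalize(rnorm(4))
    e <- to_euler(q)
    q2 <- euler_to_quat(e[["roll"]], e[["pitch"]], e[["yaw"]])
    expect_lt(min(sum((q - q2)^2), sum((q + q2)^2)), 1e-12)
  }
})

test_that("rotation preserves vector norms and recovers gravity when static", {
  set.seed(14)
  n <- 100
  Q <- t(replicate(n, quat_normalize(rnorm(4))))
  V <- matrix(rnorm(3 * n), n)
  rotated <- claudigait:::rotate_rows(Q, V)
  expect_equal(sqrt(rowSums(rotated^2)), sqrt(rowSums(V^2)), tolerance = 1e-9)

  sim <- simulate_static_poses(list(euler_to_quat(25, -40, 130)), 10,
                               wobble_deg = 0, accel_noise_sd = 0,
                               gyro_noise_sd = 0, mag_noise_sd = 0, seed = 1)
  u <- resample_linear(sim$raw)
  ori <- estimate_orientation(u)
  earth <- rotate_to_earth(u, ori, remove_gravity = FALSE)
  late <- seq(6 * 50, nrow(earth$accel_earth))
  expect_equal(colMeans(earth$accel_earth[late, ]), c(x = 0, y = 9.8, z = 0),
               tolerance = 0.05)
})

test_that("gravity removal leaves near-zero mean vertical acceleration", {
  sim <- simulate_static_poses(list(euler_to_quat(0, 60, -20)), 12, seed = 2)
  u <- filter_recording(resample_linear(sim$raw))
  earth <- rotate_to_earth(u, estimate_orientation(u))
  late <- seq(6 * 50, nrow(earth$accel_earth))
  expect_lt(abs(mean(earth$accel_earth[late, 2])), 0.2)
})

test_that("Earth-frame acceleration is invariant to the phone orientation", {
  base <- gait_sim_config(duration = 60, pain_onset = NULL, seed = 21)
  tilted <- gait_sim_config(duration = 60, pain_onset = NULL, seed = 21,
                            phone_orientation = euler_to_quat(-80, 30, 110))
  earth_of <- function(cfg) {
    sim <- simulate_walk(cfg)
    u <- filter_recording(resample_linear(sim$raw))
    rotate_to_earth(u, estimate_orientation(u))
  }
  e1 <- earth_of(base); e2 <- earth_of(tilted)
  n <- min(nrow(e1$accel_earth), nrow(e2$accel_earth))
  late <- seq(10 * 50, n)
  # cross-talk from residual attitude error, measured against the overall
  # signal scale so a near-empty axis does not inflate its own ratio
  total <- sqrt(mean(rowSums(e1$accel_earth[late, ]^2)))
  for (j in 1:3) {
    rms1 <- sqrt(mean(e1$accel_earth[late, j]^2))
    rms2 <- sqrt(mean(e2$accel_earth[late, j]^2))
    expect_lt(abs(rms1 - rms2) / total, 0.05)
  }
})

test_that("pocket-pose protocol checks recover the expected yaw and roll", {
  # test 1: screen backward then turned to face forward: yaw 0 -> 180
  sim1 <- simulate_static_poses(list(euler_to_quat(0, 0, 0),
                                     euler_to_quat(0, 0, 180)),
                                c(30, 30), seed = 5)
  u1 <- filter_recording(resample_linear(sim1$raw))
  o1 <- estimate_orientation(u1)
  t <- (seq_len(nrow(o1$euler)) - 1) / 50
  expect_lt(abs(angle_median(o1$euler[t >= 5 & t < 30, "yaw"])), 5)
  yaw2 <- angle_median(o1$euler[t >= 35, "yaw"])
  expect_lt(abs(abs(yaw2) - 180), 5)

  # test 2: horizontal, screen forward, then flipped: roll 90 -> -90, yaw 180
  sim2 <- simulate_static_poses(list(euler_to_quat(90, 0, 180),
                                     euler_to_quat(-90, 0, 180)),
                                c(30, 30), seed = 6)
  u2 <- filter_recording(resample_linear(sim2$raw))
  o2 <- estimate_orientation(u2)
  expect_lt(abs(angle_median(o2$euler[t >= 5 & t < 30, "roll"]) - 90), 5)
  expect_lt(abs(angle_median(o2$euler[t >= 35, "roll"]) + 90), 5)
  expect_lt(abs(abs(angle_median(o2$euler[t >= 5 & t < 30, "yaw"])) - 180), 5)
})

test_that("length mismatch between recording and orientation errors", {
  sim <- simulate_static_poses(list(c(1, 0, 0, 0)), 5, seed = 3)
  u <- resample_linear(sim$raw)
  ori <- estimate_orientation(u)
  ori$quaternions <- ori$quaternions[-1, , drop = FALSE]
  expect_error(rotate_to_earth(u, ori), "length")
})
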