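test_that("basic statistics match hand computation and order statistics", {
  w <- window_signals(ax = c(1, 2, 3, 4, 5), ay = rep(2, 5), az = c(-1, 0, 1, 2, 3),
                      fs = 50)
  b <- basic_stats(w)
  expect_equal(b[["mean_ax"]], 3)
  expect_equal(b[["median_ax"]], 3)
  expect_equal(b[["std_ax"]], sqrt(2.5))
  expect_equal(b[["max_ay"]], 2)
  expect_equal(b[["min_ay"]], 2)
  expect_equal(b[["std_ay"]], 0)
  expect_true(b[["min_az"]] <= b[["median_az"]] &&
                b[["median_az"]] <= b[["max_az"]])
})

test_that("the ten-bin histogram is a frequency distribution", {
  u <- seq(0, 0.99, by = 0.01)
  expect_equal(histogram10(u), rep(0.1, 10))
  expect_equal(histogram10(rep(4, 20)), c(1, rep(0, 9)))
  set.seed(41)
  for (i in 1:10) expect_equal(sum(histogram10(rnorm(77))), 1)
})

test_that("RMS ratios behave under symmetry and their squares sum to one", {
  s <- rnorm(100)
  w_eq <- window_signals(ax = s, ay = s, az = s, fs = 50)
  expect_equal(unname(rmsr(w_eq)), rep(1 / sqrt(3), 3), tolerance = 1e-12)

  w_y <- window_signals(ax = rep(0, 100), ay = rnorm(100), az = rep(0, 100),
                        fs = 50)
  expect_equal(unname(rmsr(w_y)), c(0, 1, 0))

  set.seed(42)
  for (i in 1:20) {
    w <- random_window(i)
    expect_equal(sum(rmsr(w)^2), 1, tolerance = 1e-9)
  }
})

test_that("signal magnitude area matches direct summation", {
  w1 <- window_signals(ax = rep(1, 10), ay = rep(1, 10), az = rep(1, 10), fs = 50)
  expect_equal(sma(w1), 3)
  w0 <- window_signals(ax = rep(0, 10), ay = rep(0, 10), az = rep(0, 10), fs = 50)
  expect_equal(sma(w0), 0)
  w <- random_window(99)
  expect_equal(sma(w), oracle_sma(w$ax, w$ay, w$az), tolerance = 1e-12)
})

test_that("kurtosis matches moment theory and the brute-force oracle", {
  set.seed(43)
  big <- rnorm(1e5)
  expect_equal(moment_kurtosis(big), 3, tolerance = 0.1)
  expect_equal(moment_kurtosis(rep(c(-1, 1), 50)), 1)
  x <- rnorm(200)
  expect_equal(moment_kurtosis(x), oracle_kurtosis(x), tolerance = 1e-12)
  expect_true(is.na(moment_kurtosis(rep(2, 10))))
})

test_that("skewness matches hand computation and flips sign under negation", {
  sym <- c(-2, -1, 0, 1, 2)
  expect_equal(moment_skewness(sym), 0, tolerance = 1e-12)
  expect_equal(moment_skewness(c(0, 0, 0, 1)), 0.09375 / 0.1875^1.5,
               tolerance = 1e-9)
  x <- rexp(50)
  expect_equal(moment_skewness(-x), -moment_skewness(x), tolerance = 1e-12)
})

test_that("LCSS similarity is 1 for identical cycles and 0 for disjoint ones", {
  cyc <- sin(seq(0, 2 * pi, length.out = 40))
  expect_equal(lcss_similarity(list(cyc, cyc)), 1)
  expect_equal(lcss_similarity(list(rep(0, 30), rep(10, 30)), eps = 0.5), 0)
  expect_true(is.na(lcss_similarity(list(cyc))))
})

test_that("banded LCSS matches the recursive oracle on short cycles", {
  set.seed(44)
  for (i in 1:15) {
    a <- round(rnorm(sample(6:12, 1)), 1)
    b <- round(rnorm(sample(6:12, 1)), 1)
    eps <- runif(1, 0.2, 1.5)
    delta <- sample(1:3, 1)
    expect_equal(claudigait:::lcss_length(a, b, eps, delta),
                 oracle_lcss(a, b, eps, delta))
  }
})

test_that("cadence and stride-time features are simple arithmetic", {
  ev <- gait_events(rhc = as.integer(seq(1, 500, by = 56)),
                    lhc = as.integer(seq(28, 500, by = 56)), fs = 50)
  expect_equal(cadence(ev, 10), (length(ev$rhc) + length(ev$lhc)) * 6)
  ev18 <- gait_events(rhc = as.integer(seq(1, 9 * 50, length.out = 9)),
                      lhc = as.integer(seq(25, 9 * 50 + 24, length.out = 9)),
                      fs = 50)
  expect_equal(cadence(ev18, 10), 108)
  expect_equal(cadence(gait_events(fs = 50), 10), 0)

  cyc <- data.frame(stride_time = c(1.0, 1.2))
  expect_equal(mean_stride_time(cyc), 1.1)
  expect_equal(mean_stride_time(data.frame(stride_time = 1.3)), 1.3)
  expect_true(is.na(mean_stride_time(data.frame(stride_time = numeric(0)))))
})

test_that("the swing/stance feature returns the stance percentage", {
  cyc <- data.frame(stride_time = 1.0, stance_time = 0.6)
  expect_equal(swing_stance_ratio(cyc), 60)
  expect_equal(swing_stance_ratio(data.frame(stride_time = 1, stance_time = 1)),
               100)
  expect_equal(swing_stance_ratio(cyc, mode = "difference"), -20)
  expect_true(is.na(swing_stance_ratio(
    data.frame(stride_time = 1, stance_time = NA_real_))))
})

test_that("the time block always has exactly 70 named values", {
  w <- random_window(7)
  ft <- time_features(w)
  expect_length(ft, 70)
  expect_false(any(duplicated(names(ft))))
})

test_that("features are equivariant or invariant under amplitude scaling", {
  w <- walk_fixture()$windows[[4]]
  c_scale <- 3.7
  w2 <- window_signals(ax = c_scale * w$ax, ay = c_scale * w$ay,
                       az = c_scale * w$az, fs = w$fs, events = w$events,
                       cycles = w$cycles)
  f1 <- time_features(w); f2 <- time_features(w2)
  scaled <- grep("^(max|min|mean|median|std)_|^sma$", names(f1), value = TRUE)
  expect_equal(f2[scaled], c_scale * f1[scaled], tolerance = 1e-9)
  invariant <- setdiff(names(f1), scaled)
  expect_equal(f2[invariant], f1[invariant], tolerance = 1e-7)
})

test_that("statistics match the brute-force oracles on random windows", {
  for (i in 1:30) {
    w <- random_window(1000 + i)
    b <- basic_stats(w)
    expect_equal(b[["std_mag"]], oracle_std(w$magnitude), tolerance = 1e-12)
    expect_equal(unname(rmsr(w)), oracle_rmsr(w$ax, w$ay, w$az),
                 tolerance = 1e-12)
    expect_equal(sma(w), oracle_sma(w$ax, w$ay, w$az), tolerance = 1e-12)
    expect_equal(moment_kurtosis(w$magnitude), oracle_kurtosis(w$magnitude),
                 tolerance = 1e-12)
    expect_equal(moment_skewness(w$magnitude), oracle_skewness(w$magnitude),
                 tolerance = 1e-12)
  }
})
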