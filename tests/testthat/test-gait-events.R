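test_that("heel contacts land on a constructed product minimum", {
  fs <- 50
  t <- seq(0, 9.98, by = 1 / fs)
  y_dom <- -cos(2 * pi * 2 * t)           # minima every 0.5 s
  y_rec <- y_dom
  z_rec <- rep(1, length(t))
  # sharp negative spike of the product near each third minimum
  spike_at <- which(abs((t %% 0.5) - 0.02) < 1e-9)
  z_rec[spike_at] <- 50
  y_rec[spike_at] <- -2
  hc <- detect_heel_contacts(y_dom, y_rec, z_rec, fs)
  expect_true(all(hc$contacts %in% spike_at))
})

test_that("a constant signal yields no events", {
  fs <- 50
  flat <- rep(1, 500)
  hc <- detect_heel_contacts(flat, flat, flat, fs)
  expect_length(hc$contacts, 0)
  ev <- detect_gait_events(rep(0, 500), rep(0, 500), fs)
  expect_length(ev$rhc, 0)
})

test_that("the left/right mean-amplitude rule follows its definition", {
  # y constructed so segment means between minima are 2.0 then 1.0
  y_rec <- c(rep(2, 50), rep(1, 50), rep(0, 20))
  minima <- c(1L, 51L, 101L)
  side <- assign_left_right(contacts = minima, y_rec = y_rec,
                            y_dom_minima = minima)
  expect_equal(side$rhc, c(1L, 101L))
  expect_equal(side$lhc, 51L)

  # reversed means flip the parity
  side2 <- assign_left_right(minima, c(rep(1, 50), rep(2, 50), rep(0, 20)),
                             minima)
  expect_equal(side2$lhc, c(1L, 101L))
  expect_equal(side2$rhc, 51L)
})

test_that("a tie in segment means defaults to RHC-first with a warning", {
  y <- rep(1, 120)
  expect_warning(side <- assign_left_right(c(1L, 51L, 101L), y, c(1L, 51L, 101L)),
                 "tie")
  expect_equal(side$rhc, c(1L, 101L))
})

test_that("toe-offs pick the unique qualifying extremum", {
  y <- rep(0, 100)
  y[30] <- 1    # local max between RHC=10 and LHC=50 -> LTO
  y[70] <- -1   # local min between LHC=50 and RHC=90 -> RTO
  to <- detect_toe_offs(rhc = c(10L, 90L), lhc = 50L, y_rec = y)
  expect_equal(to$rto, 70L)
  expect_equal(to$lto, 30L)
})

test_that("two contacts yield zero toe-offs without crashing", {
  to <- detect_toe_offs(rhc = 10L, lhc = 50L, y_rec = rnorm(100))
  expect_length(to$rto, 0)
})

test_that("cycle segmentation arithmetic is exact", {
  ev <- gait_events(rhc = c(1L, 51L, 101L), fs = 50)
  cyc <- segment_cycles(ev)
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$stride_time, c(1, 1))
  expect_true(all(is.na(cyc$stance_time)))

  expect_equal(nrow(segment_cycles(gait_events(fs = 50))), 0)
})

test_that("detected events preserve the within-cycle ordering", {
  wf <- walk_fixture()
  for (w in wf$windows) {
    cyc <- w$cycles
    ok <- !is.na(cyc$lto) & !is.na(cyc$lhc) & !is.na(cyc$rto)
    if (!any(ok)) next
    expect_true(all(cyc$start[ok] < cyc$lto[ok] & cyc$lto[ok] < cyc$lhc[ok] &
                      cyc$lhc[ok] < cyc$rto[ok] & cyc$rto[ok] < cyc$end[ok]))
  }
})

test_that("event detection is invariant to positive amplitude scaling", {
  wf <- walk_fixture()
  w <- wf$windows[[5]]
  ev1 <- detect_gait_events(w$ay, w$az, w$fs)
  ev2 <- detect_gait_events(7.3 * w$ay, 7.3 * w$az, w$fs)
  expect_identical(ev1$rhc, ev2$rhc)
  expect_identical(ev1$lhc, ev2$lhc)
  expect_identical(ev1$rto, ev2$rto)
})

test_that("simulated heel contacts are recovered accurately", {
  wf <- walk_fixture()
  det <- detected_contact_times(wf$windows)
  truth <- wf$sim$truth$heel_contacts$time
  covered <- truth[truth > 6 & truth < 118]
  err <- vapply(covered, function(tc) min(abs(det - tc)), numeric(1))
  expect_lte(stats::median(err), 0.1)
  expect_gte(mean(err <= 0.1), 0.9)
})

test_that("side labels match the simulated pocket side", {
  wf <- walk_fixture()
  hc <- wf$sim$truth$heel_contacts
  agree <- unlist(lapply(wf$windows, function(w) {
    s0 <- attr(w, "start_index")
    tr <- (s0 + w$events$rhc - 2) / 50
    tl <- (s0 + w$events$lhc - 2) / 50
    c(vapply(tr, function(x) hc$side[which.min(abs(hc$time - x))] == "R",
             logical(1)),
      vapply(tl, function(x) hc$side[which.min(abs(hc$time - x))] == "L",
             logical(1)))
  }))
  expect_gte(mean(agree), 0.9)
})

test_that("stance fraction and stride times are recovered from simulation", {
  wf <- walk_fixture()
  ssr <- vapply(wf$windows, function(w) swing_stance_ratio(w$cycles),
                numeric(1))
  truth_pct <- 100 * wf$sim$truth$stance_fraction
  expect_lt(abs(mean(ssr, na.rm = TRUE) - truth_pct), 10)

  st <- unlist(lapply(wf$windows, function(w) w$cycles$stride_time))
  expect_lt(abs(mean(st) - mean(wf$sim$truth$stride_times)), 0.05)
})

test_that("detected stride time regresses on truth across walking speeds", {
  strides <- seq(0.95, 1.35, length.out = 6)
  res <- t(vapply(seq_along(strides), function(i) {
    cfg <- gait_sim_config(duration = 50, stride_time_mean = strides[i],
                           pain_onset = NULL, seed = 300 + i)
    sim <- simulate_walk(cfg)
    walk <- process_trial(sim$raw, "P", "T")
    kept <- drop_cycleless(attach_window_events(make_windows(walk)))
    st <- unlist(lapply(kept, function(w) w$cycles$stride_time))
    c(truth = mean(sim$truth$stride_times), det = mean(st))
  }, numeric(2)))
  fit <- stats::lm(res[, "det"] ~ res[, "truth"])
  expect_gt(stats::coef(fit)[2], 0.9)
  expect_lt(stats::coef(fit)[2], 1.1)
  expect_gte(summary(fit)$r.squared, 0.9)
})
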