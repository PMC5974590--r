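test_that("angular velocity is zero for a still eye and d/T for linear drift", {
  still <- make_dwell_trace(0, 0, 500)
  v <- angular_velocity(still, the_display, 60)
  expect_true(all(v[!is.na(v)] == 0))
  expect_true(any(!is.na(v)))

  # 2 degrees of horizontal drift over 1 s -> 2 deg/s in the interior
  dt <- 4; t <- seq(0, 1000 - dt, by = dt)
  ax <- 2 * t / 1000
  xy <- angles_to_point(ax, rep(0, length(t)), the_display, 60)
  drift <- make_samples(t, xy[, 1], xy[, 2])
  v <- angular_velocity(drift, the_display, 60, ivt_params(velocity_window_ms = 20))
  interior <- v[10:(length(v) - 10)]
  expect_true(all(abs(interior - 2) < 1e-6))
})

test_that("angular velocity matches a brute-force windowed oracle", {
  trace <- rbind(make_dwell_trace(0, 0, 200), make_dwell_trace(3, 1, 200))
  trace$t_ms <- (seq_len(nrow(trace)) - 1) * (10 / 3)
  trace$val_l[25:27] <- 4L; trace$val_r[25:27] <- 4L  # punch an invalid hole
  p <- ivt_params()
  v <- angular_velocity(trace, the_display, 60, p)
  valid <- sample_is_valid(trace, the_display)
  t <- trace$t_ms
  ax <- oracle_axis_angles(trace$x_px, 960, 60)
  ay <- oracle_axis_angles(trace$y_px, 540, 60)
  for (i in seq_along(t)) {
    in_win <- which(t >= t[i] - 10 & t <= t[i] + 10)
    j0 <- min(in_win); j1 <- max(in_win)
    expected <- if (!valid[i] || any(!valid[in_win]) || j1 <= j0) {
      NA_real_
    } else {
      sqrt((ax[j1] - ax[j0])^2 + (ay[j1] - ay[j0])^2) / ((t[j1] - t[j0]) / 1000)
    }
    expect_equal(v[i], expected, tolerance = 1e-9)
  }
})

test_that("a stationary noise-free trace yields exactly one spanning fixation", {
  trace <- make_dwell_trace(1, -1, 2000)
  fx <- classify_fixations(trace, the_display, 60)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$start_ms, trace$t_ms[1])
  expect_equal(fx$end_ms, trace$t_ms[nrow(trace)])
  expect_equal(fx$n_valid, nrow(trace))
})

test_that("two dwells joined by an instantaneous jump give two fixations", {
  trace <- rbind(make_dwell_trace(0, 0, 500), make_dwell_trace(5, 0, 500))
  trace$t_ms <- (seq_len(nrow(trace)) - 1) * (10 / 3)
  fx <- classify_fixations(trace, the_display, 60)
  expect_equal(nrow(fx), 2)
  cen <- point_angles(fx$centroid_x, fx$centroid_y, the_display, 60)
  expect_equal(unname(cen[, 1]), c(0, 5), tolerance = 1e-6)
})

test_that("a 40 ms dwell between saccades is below minimum duration", {
  trace <- rbind(make_dwell_trace(-5, 0, 500), make_dwell_trace(0, 0, 40),
                 make_dwell_trace(5, 0, 500))
  trace$t_ms <- (seq_len(nrow(trace)) - 1) * (10 / 3)
  fx <- classify_fixations(trace, the_display, 60)
  expect_equal(nrow(fx), 2)  # the 40 ms dwell contributes no event
  cen <- point_angles(fx$centroid_x, fx$centroid_y, the_display, 60)
  expect_false(any(abs(cen[, 1]) < 2))
})

test_that("speeds clearly above threshold break fixations; below do not", {
  dt <- 4; t <- seq(0, 996, by = dt)
  mk <- function(speed) {
    ax <- speed * t / 1000
    xy <- angles_to_point(ax, rep(0, length(t)), the_display, 60)
    make_samples(t, xy[, 1], xy[, 2])
  }
  expect_equal(nrow(classify_fixations(mk(29), the_display, 60)), 1)
  expect_equal(nrow(classify_fixations(mk(31), the_display, 60)), 0)
})

test_that("invalid gaps are bridged only when short and spatially consistent", {
  gap_trace <- function(gap_ms, ax2) {
    a <- make_dwell_trace(0, 0, 300)
    g <- make_dwell_trace(0, 0, gap_ms, media = "gap")
    g$val_l <- 4L; g$val_r <- 4L; g$x_px <- NA; g$y_px <- NA; g$media <- "T1"
    b <- make_dwell_trace(ax2, 0, 300)
    out <- rbind(a, g, b)
    out$t_ms <- (seq_len(nrow(out)) - 1) * (10 / 3)
    out
  }
  bridged <- classify_fixations(gap_trace(50, 0), the_display, 60)
  expect_equal(nrow(bridged), 1)
  expect_gt(bridged$duration_ms, 600)

  split_time <- classify_fixations(gap_trace(100, 0), the_display, 60)
  expect_equal(nrow(split_time), 2)

  split_space <- classify_fixations(gap_trace(50, 2), the_display, 60)
  expect_equal(nrow(split_space), 2)
})

test_that("exported fixation indices are adopted, invalid samples discarded", {
  s <- make_samples(0:5 * 10, c(100, 102, 104, 300, 302, 304),
                    c(200, 202, 204, 400, 402, 404),
                    fix_idx = c(1, 1, 1, 2, 2, 2))
  rec <- gaze_recording("p", s)
  fx <- adopt_exported_fixations(rec, the_display)
  expect_equal(nrow(fx), 2)
  expect_equal(fx$centroid_x, c(102, 302))

  # an off-screen sample inside an event is dropped from the centroid
  s2 <- s
  s2$x_px[2] <- 5000
  fx2 <- adopt_exported_fixations(gaze_recording("p", s2), the_display)
  expect_equal(fx2$n_valid[1], 2)
  expect_equal(fx2$centroid_x[1], mean(c(100, 104)))  # hand-computed mean
  expect_equal(fx2$n_samples[1], 3)

  s3 <- s
  s3$fix_idx <- c(1L, 2L, 1L, 2L, 2L, 2L)
  expect_warning(adopt_exported_fixations(gaze_recording("p", s3), the_display),
                 "non-contiguous")
})

test_that("participant_fixations falls back to I-VT without an index column", {
  sim <- simulate_participant(simulation_config(seed = 5, noise_sd_deg = c(0.05, 0.05)))
  rec <- sim$recording
  expect_true(all(is.na(rec$samples$fix_idx)))
  via_wrapper <- participant_fixations(rec, the_display, 60)
  direct <- classify_fixations(rec$samples, the_display, 60)
  expect_equal(via_wrapper, direct)
  # with indices present the wrapper adopts them instead
  rec$samples$fix_idx <- 1L
  adopted <- participant_fixations(rec, the_display, 60)
  expect_equal(nrow(adopted), 1)
})

test_that("fixations are disjoint, ordered, and fit inside the trace", {
  for (seed in 1:5) {
    sim <- simulate_participant(simulation_config(
      seed = seed, noise_sd_deg = c(0.15, 0.18), noise_ar1 = 0.4,
      dropout_prob = 0.08, trial_compliance = 0.8))
    fx <- classify_fixations(sim$recording$samples, the_display, 60)
    if (nrow(fx) > 1) {
      expect_true(all(diff(fx$start_ms) > 0))
      expect_true(all(fx$start_ms[-1] >= fx$end_ms[-nrow(fx)]))
    }
    expect_lte(sum(fx$duration_ms), diff(range(sim$recording$samples$t_ms)))
  }
})

test_that("detected fixations match generated dwell episodes on low-noise traces", {
  for (seed in 1:100) {
    sim <- simulate_participant(simulation_config(
      seed = 1000 + seed, noise_sd_deg = c(0.04, 0.04), noise_ar1 = 0.3,
      dropout_prob = 0.01))
    fx <- classify_fixations(sim$recording$samples, the_display, 60)
    expected <- sum(sim$truth$episodes$duration_ms >= 90)
    expect_equal(nrow(fx), expected,
                 info = sprintf("seed %d", 1000 + seed))
  }
})

test_that("raising the velocity threshold never decreases total fixation time", {
  for (seed in 1:6) {
    sim <- simulate_participant(simulation_config(
      seed = 50 + seed, noise_sd_deg = c(0.08, 0.08), noise_ar1 = 0.3))
    totals <- vapply(c(20, 30, 50, 100), function(thr) {
      fx <- classify_fixations(sim$recording$samples, the_display, 60,
                               ivt_params(velocity_threshold_deg_s = thr))
      sum(fx$duration_ms)
    }, 0)
    expect_true(all(diff(totals) >= 0), info = sprintf("seed %d", 50 + seed))
  }
})
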