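test_that("a single noiseless spot yields one track at sub-pixel accuracy", {
  stack <- single_motor_stack(v = 0.3, n_frames = 60)
  tr <- detect_and_link(stack, intensity_threshold = 30)
  expect_identical(tr$n_tracks, 1L)
  trk <- tr$tracks
  expect_identical(nrow(trk), 60L)
  truth <- 1 + 0.3 * trk$t_s
  expect_lt(max(abs(trk$x_um - truth)), 0.2 * stack$pixel_um)
})

test_that("a background-only stack yields zero tracks", {
  ts <- parametric_trajectories(0.3, 0.25, 0, 10, 20, seed = 1)
  stack <- render_stack(ts, optics_config(n_frames = 40, seed = 3))
  tr <- detect_and_link(stack)
  expect_identical(tr$n_tracks, 0L)
})

test_that("most ground-truth runs are recovered as tracks", {
  ts <- parametric_trajectories(0.33, 0.28, binding_rate_per_um = 0.14,
                                length_um = 12, duration_s = 120, seed = 55)
  stack <- render_stack(ts, optics_config(n_frames = 600, seed = 56))
  tr <- suppressWarnings(detect_and_link(stack))
  p <- ts$paths
  eligible <- p[p$t1_s - p$t0_s >= 1 & p$t1_s < 120, ]
  expect_gt(nrow(eligible), 30)
  # a run counts as recovered when some track's midpoint lies on it
  mids <- vapply(split(tr$tracks, tr$tracks$track_id), function(d) {
    k <- ceiling(nrow(d) / 2)
    c(d$t_s[k], d$x_um[k])
  }, numeric(2))
  hit <- vapply(seq_len(nrow(eligible)), function(i) {
    dt <- mids[1, ] - eligible$t0_s[i]
    xr <- eligible$x0_um[i] + 0.33 * dt
    any(dt >= 0 & dt <= eligible$t1_s[i] - eligible$t0_s[i] &
        abs(mids[2, ] - xr) < 0.3)
  }, logical(1))
  expect_gt(mean(hit), 0.8)
})

test_that("mean displacement slope equals the velocity for exact tracks", {
  xs <- lapply(1:30, function(i) 0.5 + 0.33 * 0.2 * (0:19))
  tr <- make_track_set(xs)
  md <- mean_displacement_velocity(tr)
  expect_equal(md$velocity_um_s, 0.33, tolerance = 1e-10)

  static <- make_track_set(lapply(1:25, function(i) rep(2, 10)))
  expect_equal(mean_displacement_velocity(static)$velocity_um_s, 0,
               tolerance = 1e-12)
})

test_that("mean displacement velocity tolerates localization noise", {
  set.seed(71)
  xs <- lapply(1:60, function(i)
    1 + 0.4 * 0.2 * (0:24) + stats::rnorm(25, 0, 0.04))
  md <- mean_displacement_velocity(make_track_set(xs))
  expect_lt(abs(md$velocity_um_s - 0.4) / 0.4, 0.05)
})

test_that("mean displacement preconditions are enforced", {
  few <- make_track_set(lapply(1:5, function(i) 1:6 * 0.1))
  expect_error(mean_displacement_velocity(few), "tracks")
  single <- make_track_set(lapply(1:25, function(i) 0.5))
  expect_error(mean_displacement_velocity(single), "single-frame")
})

test_that("run-length CDF fit recovers an exponential mean", {
  set.seed(81)
  x <- stats::rexp(300, 1 / 1.18)
  fit <- runlength_cdf_fit(x, min_observable_um = 0)
  expect_lt(abs(fit$run_length_um - 1.18), 3 * fit$se)
  expect_identical(fit$n, 300L)
})

test_that("degenerate length distributions are rejected with a diagnostic", {
  expect_error(runlength_cdf_fit(rep(1.5, 100)), "identical|sd")
  expect_error(runlength_cdf_fit(stats::rexp(20, 1)), "need >=")
})

test_that("truncation is handled through the detection floor", {
  set.seed(82)
  x <- stats::rexp(4000, 1 / 2)
  x <- x[x >= 0.3]
  fit <- runlength_cdf_fit(x, min_observable_um = 0.3)
  expect_lt(abs(fit$run_length_um - 2) / 2, 0.1)
})

test_that("the fitted mean is invariant to raising the floor", {
  set.seed(83)
  x <- stats::rexp(3000, 1 / 1.2)
  f1 <- runlength_cdf_fit(x[x >= 0.2], min_observable_um = 0.2)
  f2 <- runlength_cdf_fit(x[x >= 0.8], min_observable_um = 0.8)
  expect_lt(abs(f1$run_length_um - f2$run_length_um),
            3 * sqrt(f1$se^2 + f2$se^2))
})

test_that("SPT and correlation imaging agree on a shared low-density
           fixture", {
  # density low enough that both methods are inside their preconditions
  ts <- parametric_trajectories(0.3, 0.25, binding_rate_per_um = 0.1,
                                length_um = 16, duration_s = 160,
                                seed = 120)
  stack <- render_stack(ts, optics_config(n_frames = 800, seed = 121))
  kymo <- background_subtract(make_kymograph(stack))
  est <- extract_velocity_runlength(
    spatiotemporal_correlation(kymo, max_lag_s = 8))
  tr <- suppressWarnings(detect_and_link(stack))
  md <- mean_displacement_velocity(tr)
  rl <- runlength_cdf_fit(track_run_lengths(tr, drop_last_frame = TRUE),
                          min_observable_um = 0.3, min_tracks = 30)
  # joint 95% intervals on the differences
  expect_lt(abs(md$velocity_um_s - est$velocity_um_s),
            2 * sqrt(md$se^2 + est$velocity_se^2) + 0.01)
  expect_lt(abs(rl$run_length_um - est$run_length_um),
            2 * sqrt(rl$se^2 + est$run_length_se^2) + 0.1)
})
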