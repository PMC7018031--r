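test_that("parametric generator handles degenerate settings", {
  empty <- parametric_trajectories(0.3, 0.25, 0, 10, 100, seed = 1)
  expect_identical(nrow(empty$paths), 0L)

  still <- parametric_trajectories(0, 0.5, 1, 10, 200, seed = 2)
  expect_true(all(still$paths$x1_um == still$paths$x0_um))
  # uncensored lifetimes follow the exponential law (KS test)
  life <- with(still$paths[!still$paths$censored, ], t1_s - t0_s)
  expect_gt(length(life), 200)
  ks <- stats::ks.test(life, "pexp", rate = 0.5)
  expect_gt(ks$p.value, 0.01)
})

test_that("mean run length approaches v/omega_D as samples grow", {
  ts <- parametric_trajectories(0.3, 0.25, 3, 40, 200, seed = 3)
  # restrict to runs born well before the plus end and well before the end
  # of the window, so censoring cannot bias the sample of completed runs
  p <- ts$paths[!ts$paths$censored & ts$paths$x0_um < 34 &
                  ts$paths$t0_s < 180, ]
  len <- p$x1_um - p$x0_um
  expect_gt(length(len), 2000)
  expect_equal(mean(len), 1.2, tolerance = 3 / sqrt(length(len)))
})

test_that("rendering conserves photons in expectation", {
  stack <- single_motor_stack(v = 0, n_frames = 20)
  totals <- apply(stack$frames, 3, sum)
  # every frame carries the full photon budget of the one motor, up to
  # integer digitization of the faint spot tails
  expect_equal(unname(totals), rep(2000, 20), tolerance = 5e-3)
  # brightest pixel sits at the motor position (x = 1 um -> pixel 13)
  fr <- stack$frames[, , 1]
  peak <- which(fr == max(fr), arr.ind = TRUE)
  expect_equal(unname(peak[1, "col"]), 13)
  expect_equal(unname(peak[1, "row"]), (dim(fr)[1] + 1) / 2)
})

test_that("label thinning halves the mean signal at fraction one half", {
  ts <- parametric_trajectories(0.25, 0.25, 1.5, 10, 40, seed = 9)
  mean_sig <- function(frac, seed) {
    oc <- optics_config(n_frames = 200, labeled_fraction = frac,
                        camera_offset = 0, background_photons = 0,
                        seed = seed)
    mean(apply(render_stack(ts, oc)$frames, 3, sum))
  }
  full <- mean_sig(1, 31)
  half <- mean(vapply(32:36, function(s) mean_sig(0.5, s), numeric(1)))
  expect_equal(half / full, 0.5, tolerance = 0.1)
})

test_that("identical seeds render bit-identical stacks", {
  ts <- parametric_trajectories(0.3, 0.25, 1, 8, 20, seed = 5)
  oc <- optics_config(n_frames = 50, seed = 77)
  expect_identical(render_stack(ts, oc)$frames, render_stack(ts, oc)$frames)
})

test_that("trajectories outside the field of view raise a geometry error", {
  ts <- parametric_trajectories(0.3, 0.25, 1, 20, 50, seed = 6)
  expect_error(render_stack(ts, optics_config(n_frames = 10), length_um = 5),
               "field of view")
})

test_that("kymograph of a uniform stack is constant", {
  ts <- parametric_trajectories(0.3, 0.25, 0, 10, 20, seed = 1)  # empty
  oc <- optics_config(n_frames = 30, shot_noise = FALSE,
                      background_photons = 50, camera_offset = 100)
  kymo <- make_kymograph(render_stack(ts, oc))
  expect_equal(stats::var(as.vector(kymo$intensity)), 0)
  expect_equal(unique(as.vector(kymo$intensity)), 150)
})

test_that("a single moving motor leaves a kymograph ridge of slope v", {
  stack <- single_motor_stack(v = 0.3, n_frames = 100)
  kymo <- make_kymograph(stack)
  ridge <- kymo$x_um[apply(kymo$intensity, 2, which.max)]
  t_mid <- (seq_len(ncol(kymo$intensity)) - 0.5) * kymo$dt_s
  slope <- stats::coef(stats::lm(ridge ~ t_mid))[2]
  expect_equal(unname(slope), 0.3, tolerance = 0.02)
})

test_that("sampling bands outside the image raise a geometry error", {
  stack <- single_motor_stack(n_frames = 5)
  expect_error(make_kymograph(stack, background_offset_px = 50),
               "outside the image")
})
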