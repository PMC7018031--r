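make_kymo <- function(intensity, bg_mean = NULL, dt = 0.2, pix = 0.08,
                      subtracted = FALSE) {
  structure(list(intensity = intensity,
                 x_um = (seq_len(nrow(intensity)) - 0.5) * pix,
                 dt_s = dt, pixel_um = pix,
                 bg_mean = bg_mean, bg_sd = NULL, n_bg_samples = NA,
                 background_subtracted = subtracted),
            class = "kymograph")
}

test_that("background subtraction removes a constant offset exactly", {
  signal <- matrix(stats::runif(50 * 120, 0, 10), 50, 120)
  kymo <- make_kymo(signal + 37, bg_mean = rep(37, 120))
  out <- background_subtract(kymo)
  expect_equal(out$intensity, signal)
  expect_true(out$background_subtracted)

  # pure background: zero mean per frame, negatives retained
  noise <- matrix(stats::rnorm(50 * 120, 100, 3), 50, 120)
  kb <- make_kymo(noise, bg_mean = colMeans(noise))
  sub <- background_subtract(kb)
  expect_equal(colMeans(sub$intensity), rep(0, 120), tolerance = 1e-10)
  expect_true(any(sub$intensity < 0))

  expect_error(background_subtract(make_kymo(signal)), "background")
})

test_that("FCS refuses signals without number fluctuations", {
  const <- make_kymo(matrix(5, 40, 200), bg_mean = rep(0, 200),
                     subtracted = TRUE)
  expect_error(fcs_density(const, 5, 5), "constant|fluctuation|G\\(0")
  expect_error(fcs_density(corr_fixture()$kymo, 5, 2), "total_conc")
})

test_that("FCS recovers particle number and scales by the labeled ratio", {
  # mean ~10 labeled motors on 5 um; unlabeled spike 50x
  ests <- vapply(1:20, function(s) {
    ts <- parametric_trajectories(0.3, 0.25, binding_rate_per_um = 0.5,
                                  length_um = 5, duration_s = 120,
                                  seed = 500 + s)
    stack <- render_stack(ts, optics_config(n_frames = 600, seed = 600 + s))
    kymo <- background_subtract(make_kymograph(stack))
    d <- fcs_density(kymo, labeled_conc_nM = 5, total_conc_nM = 250)
    c(d$density_per_um, d$labeled_per_um, mean_motor_count(ts) / 5)
  }, numeric(3))
  # scaling factor 50 applied
  expect_equal(ests[1, ] / ests[2, ], rep(50, 20))
  # mean total density ~ 50x the true labeled density, within 15%
  truth <- 50 * mean(ests[3, ])
  expect_lt(abs(mean(ests[1, ]) - truth) / truth, 0.15)
})

test_that("estimated motor number is linear in the true motor number", {
  levels <- c(0.3, 0.6, 1.2, 2.4)   # binding rates -> one decade of N
  est <- truth <- numeric(length(levels))
  for (i in seq_along(levels)) {
    Ns <- vapply(1:4, function(r) {
      ts <- parametric_trajectories(0.3, 0.25, levels[i], 8, 120,
                                    seed = 700 + 10 * i + r)
      stack <- render_stack(ts, optics_config(n_frames = 600,
                                              seed = 800 + 10 * i + r))
      kymo <- background_subtract(make_kymograph(stack))
      c(fcs_density(kymo, 5, 5)$N, mean_motor_count(ts))
    }, numeric(2))
    est[i] <- mean(Ns[1, ]); truth[i] <- mean(Ns[2, ])
  }
  expect_gt(summary(stats::lm(est ~ truth))$r.squared, 0.98)
})

test_that("immobile motors give a stationary correlation peak", {
  ts <- parametric_trajectories(0, 0.25, binding_rate_per_um = 1, 10, 120,
                                seed = 23)
  stack <- render_stack(ts, optics_config(n_frames = 600, seed = 24))
  kymo <- background_subtract(make_kymograph(stack))
  surf <- spatiotemporal_correlation(kymo, max_lag_s = 6)
  f <- surf$fits[surf$fits$ok & surf$fits$tau_s > 0, ]
  expect_gt(nrow(f), 10)
  expect_lt(max(abs(f$x_peak_um)), kymo$pixel_um)
})

test_that("coherent transport without unbinding keeps the area flat and
           the peak at v tau", {
  # constant number of motors moving at v on a wrapping track: the peak
  # drifts at v while nothing ever unbinds, so A(tau) does not decay
  set.seed(30)
  L <- 16; pix <- 0.08; nx <- L / pix; Tn <- 300; v <- 0.3; dt <- 0.2
  x0 <- stats::runif(12, 0, L)
  xs <- (seq_len(nx) - 0.5) * pix
  intensity <- vapply(seq_len(Tn), function(f) {
    xm <- (x0 + v * (f - 0.5) * dt) %% L
    rowSums(vapply(xm, function(m) {
      d <- abs(xs - m); d <- pmin(d, L - d)
      120 * exp(-d^2 / (2 * 0.13^2))
    }, numeric(nx))) + stats::rnorm(nx, 0, 2)
  }, numeric(nx))
  kymo <- make_kymo(intensity, bg_mean = rep(0, Tn), subtracted = TRUE)
  surf <- spatiotemporal_correlation(kymo, max_lag_s = 6)
  f <- surf$fits[surf$fits$ok & surf$fits$tau_s > 0, ]
  expect_gt(nrow(f), 20)
  expect_lt(max(abs(f$x_peak_um - v * f$tau_s)), kymo$pixel_um)
  est <- extract_velocity_runlength(surf)
  expect_lt(abs(est$velocity_um_s - v) / v, 0.05)
  expect_true(est$undetermined || est$run_length_um > 10)
})

test_that("velocity and run length are recovered from a rendered stack", {
  fx <- corr_fixture()
  surf <- spatiotemporal_correlation(fx$kymo, max_lag_s = 8)
  est <- extract_velocity_runlength(surf)
  expect_lt(abs(est$velocity_um_s - 0.3) / 0.3, 0.05)
  expect_lt(abs(est$run_length_um - 1.2) / 1.2, 0.25)
  expect_gt(est$velocity_r2, 0.99)
})

test_that("recovery is unbiased across velocity and run-length settings", {
  cases <- data.frame(v = c(0.1, 0.3, 0.6), rl = c(0.6, 1.2, 2.4))
  for (i in seq_len(nrow(cases))) {
    v <- cases$v[i]; rl <- cases$rl[i]
    errs <- vapply(1:20, function(s) {
      ts <- parametric_trajectories(v, v / rl, 0.75, 14, 160,
                                    seed = 900 + 100 * i + s)
      stack <- render_stack(ts, optics_config(n_frames = 800,
                                              seed = 2900 + 100 * i + s))
      kymo <- background_subtract(make_kymograph(stack))
      est <- extract_velocity_runlength(
        spatiotemporal_correlation(kymo, max_lag_s = min(10, 2.5 * rl / v)))
      c(abs(est$velocity_um_s - v) / v,
        abs(est$run_length_um - rl) / rl)
    }, numeric(2))
    expect_lt(stats::median(errs[1, ]), 0.05)
    expect_lt(stats::median(errs[2, ]), 0.15)
  }
})

test_that("photobleaching adds to the fitted decay rate", {
  ts <- parametric_trajectories(0.3, 0.25, 0.75, 12, 100, seed = 915)
  oc <- optics_config(n_frames = 500, bleach_rate = 0.2, seed = 916)
  kymo <- background_subtract(make_kymograph(render_stack(ts, oc)))
  est <- extract_velocity_runlength(
    spatiotemporal_correlation(kymo, max_lag_s = 6))
  # decay ~ omega_D + bleach = 0.45, well above omega_D alone
  expect_gt(est$detachment_rate, 0.33)
  expect_lt(est$detachment_rate, 0.60)
})
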