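analytic_series <- function(conc_nM, params = table1_params(), noise = 0) {
  # exact low-density expectations from the attachment calibration
  c3 <- nM_to_per_um3(conc_nM)
  a <- analytic_low_density(params)
  dens <- params$omega_A0 * c3 / params$omega_D * params$n_lanes *
    (1000 / params$motor_step_nm)
  jitter <- function(x) x * (1 + noise * stats::rnorm(length(x)))
  concentration_series(conc_nM,
                       density = jitter(dens),
                       density_se = pmax(noise, 0.005) * dens,
                       velocity = jitter(rep(a$v0_um_s, length(conc_nM))),
                       velocity_se = pmax(noise, 0.005) * a$v0_um_s,
                       runlength = jitter(rep(a$run_length_um,
                                              length(conc_nM))),
                       runlength_se = pmax(noise, 0.005) * a$run_length_um)
}

test_that("stage-1 fit recovers the elementary rates from a linear series", {
  ser <- analytic_series(c(2, 5, 10, 20, 50))
  s1 <- fit_low_density(ser, table1_params())
  expect_equal(s1$omega_D, 0.25, tolerance = 1e-6)
  expect_equal(s1$step_rate, 37.5, tolerance = 1e-6)
  expect_equal(s1$omega_A0, 1.53e-4, tolerance = 1e-6)
})

test_that("stage-1 fit recovers the rates from simulated observables", {
  p <- table1_params()
  ser <- predict_series(p, c(2, 5, 10, 20), reps = 2, seed = 11,
                        lattice_length_um = 20, duration_s = 250,
                        burn_in_s = 70, min_uncensored = 50)
  s1 <- fit_low_density(ser, p)
  expect_lt(abs(s1$omega_D - 0.25) / 0.25, 0.1)
  expect_lt(abs(s1$step_rate - 37.5) / 37.5, 0.05)
  expect_lt(abs(s1$omega_A0 - 1.53e-4) / 1.53e-4, 0.2)
})

test_that("stage-1 fit refuses series outside the linear regime", {
  conc <- c(10, 100, 400, 1000, 2000)
  c3 <- nM_to_per_um3(conc)
  sat <- 800 * c3 / (c3 + 150)          # saturating density curve
  ser <- concentration_series(conc, sat, 0.01 * sat,
                              rep(0.3, 5), rep(0.003, 5),
                              rep(1.2, 5), rep(0.012, 5))
  expect_error(fit_low_density(ser, table1_params()),
               "non-linear|restrict")
})

test_that("degenerate series are rejected", {
  expect_error(fit_low_density(analytic_series(c(5, 10)), table1_params()),
               ">= 3")
  zero <- concentration_series(c(1, 2, 4), rep(0, 3), rep(1e-3, 3),
                               rep(0, 3), rep(1e-3, 3),
                               rep(0, 3), rep(1e-3, 3))
  expect_error(fit_low_density(zero, table1_params()), "zero|positive")
})

test_that("predicted densities vanish without attachment", {
  p <- kinetic_params(omega_A0 = 0)
  ser <- predict_series(p, c(10, 100), reps = 1, seed = 2,
                        lattice_length_um = 3, duration_s = 30,
                        burn_in_s = 5)
  expect_equal(ser$density, c(0, 0))
})

test_that("the no-transport control reproduces the Langmuir isotherm", {
  p <- kinetic_params(motor_size_nm = 8, step_rate = 0, omega_A0 = 1.53e-4,
                      omega_D = 0.25, omega_DC = 0.25, n_lanes = 1)
  ser <- suppressWarnings(
    predict_series(p, c(200, 800), reps = 2, seed = 17,
                   lattice_length_um = 8, duration_s = 200,
                   burn_in_s = 40, min_uncensored = 50))
  k <- 1.53e-4 * nM_to_per_um3(ser$conc_nM)
  expected <- 125 * k / (k + 0.25)
  expect_lt(max(abs(ser$density - expected) / expected), 0.05)
})

test_that("density grows sublinearly once binding sites saturate", {
  p <- table1_params()
  ser <- predict_series(p, c(20, 200, 2000), reps = 1, seed = 23,
                        lattice_length_um = 4, duration_s = 60,
                        burn_in_s = 20)
  slopes <- diff(ser$density) / diff(nM_to_per_um3(ser$conc_nM))
  expect_lt(slopes[2], 0.7 * slopes[1])
})

test_that("grid bounds and empty grids are rejected", {
  ser <- analytic_series(c(5, 10, 20))
  p <- table1_params()
  expect_error(grid_search_fit(ser, p, lanes = integer(0)), "empty grid")
  expect_error(grid_search_fit(ser, p, lanes = 14), "bounds")
  expect_error(grid_search_fit(ser, p, ratios = 11), "bounds")
  expect_error(grid_search_fit(ser, p, ranges = 25), "bounds")
})

test_that("a single-triple grid scores near the noise floor", {
  p <- table1_params()
  concs <- c(100, 800)
  truth <- predict_series(p, concs, reps = 2, seed = 31,
                          lattice_length_um = 4, duration_s = 60,
                          burn_in_s = 20)
  set.seed(32)
  obs <- truth
  for (f in c("density", "velocity", "runlength")) {
    obs[[f]] <- truth[[f]] * stats::rnorm(2, 1, 0.05)
    obs[[paste0(f, "_se")]] <- 0.05 * truth[[f]]
  }
  fr <- grid_search_fit(obs, p, lanes = 13, ranges = 0, ratios = 3,
                        reps = 2, seed = 33, lattice_length_um = 4,
                        duration_s = 60, burn_in_s = 20)
  expect_identical(fr$best$n_lanes, 13)
  expect_identical(nrow(fr$loss_table), 1L)
  # 6 residuals of unit scale: the loss should sit near its chi-square scale
  expect_lt(fr$loss, 30)
})
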