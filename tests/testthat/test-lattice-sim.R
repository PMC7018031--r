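test_that("configuration errors are caught before simulating", {
  expect_error(lattice_config(10, duration_s = -5), "duration_s")
  expect_error(lattice_config(0, duration_s = 10), "lattice_length_um")
  expect_error(lattice_config(1, 10, boundary = "ring", langmuir = TRUE,
                              n_motors = 3, concentration = 1),
               "mutually exclusive")
  expect_error(lattice_config(10, 10, burn_in_s = 20), "burn_in")
  expect_warning(
    simulate_traffic(table1_params(),
                     lattice_config(2, 30, concentration = 0.3,
                                    burn_in_s = 5, seed = 1)),
    "end-censoring")
})

test_that("without stepping no motor moves and velocity is zero", {
  p <- kinetic_params(step_rate = 0)
  cfg <- lattice_config(5, 60, concentration = 3, burn_in_s = 5, seed = 2)
  ts <- simulate_traffic(p, cfg)
  expect_gt(nrow(ts$runs), 50)
  expect_true(all(ts$runs$unbind_site == ts$runs$bind_site))
  expect_identical(ensemble_velocity(ts)$velocity_um_s, 0)
})

test_that("identical seeds give bit-identical event histories", {
  p <- table1_params()
  cfg <- lattice_config(5, 40, concentration = 5, burn_in_s = 5, seed = 99)
  ts1 <- simulate_traffic(p, cfg)
  ts2 <- simulate_traffic(p, cfg)
  expect_identical(ts1$runs, ts2$runs)
  cfg2 <- lattice_config(5, 40, concentration = 5, burn_in_s = 5, seed = 100)
  expect_false(identical(simulate_traffic(p, cfg2)$runs, ts1$runs))
})

test_that("run records respect unidirectional motion and time order", {
  p <- table1_params()
  cfg <- lattice_config(6, 60, concentration = 60, burn_in_s = 5, seed = 5)
  runs <- simulate_traffic(p, cfg)$runs
  expect_gt(nrow(runs), 500)
  expect_true(all(runs$unbind_time_s >= runs$bind_time_s))
  expect_true(all(runs$unbind_site >= runs$bind_site))
  expect_true(all(runs$lane >= 1 & runs$lane <= 13))
})

test_that("hard-core exclusion holds in every occupancy snapshot", {
  # crowded conditions, footprint of 2 sites
  p <- table1_params()
  cfg <- lattice_config(3, 40, concentration = 600, conc_unit = "nM",
                        burn_in_s = 5, snapshot_interval_s = 2, seed = 8)
  ts <- simulate_traffic(p, cfg)
  sn <- ts$snapshots
  expect_gt(nrow(sn), 1000)
  f <- p$footprint_sites
  for (tt in unique(sn$time_s)) {
    s <- sn[sn$time_s == tt, ]
    occupied <- paste(rep(s$lane, each = f),
                      as.vector(vapply(s$site, function(x) x - seq_len(f) + 1,
                                       numeric(f))))
    expect_false(anyDuplicated(occupied) > 0)
  }
  # motors never move backward between snapshots
  for (id in unique(sn$motor[duplicated(sn$motor)])) {
    tr <- sn[sn$motor == id, ]
    tr <- tr[order(tr$time_s), ]
    expect_true(all(diff(tr$site) >= 0))
  }
})

test_that("ring exclusion process matches the exact stationary velocity", {
  # brute-force enumeration over all configurations confirms the closed form
  for (L in 5:8) {
    for (N in c(2, L - 2)) {
      expect_equal(ring_step_fraction_enum(L, N), (L - N) / (L - 1),
                   tolerance = 1e-12)
    }
  }
  # simulation agrees with the enumerated value within 3 SE
  p <- kinetic_params(motor_size_nm = 8, step_rate = 10, n_lanes = 1)
  cfg <- lattice_config(6 * 0.008, 4000, boundary = "ring",
                        langmuir = FALSE, n_motors = 3, burn_in_s = 20,
                        seed = 21)
  ev <- ensemble_velocity(simulate_traffic(p, cfg))
  v_exact <- 10 * ring_step_fraction_enum(6, 3) * 0.008
  expect_lt(abs(ev$velocity_um_s - v_exact), 3 * ev$se)
})

test_that("stationary occupancy obeys the Langmuir isotherm without transport", {
  p <- kinetic_params(motor_size_nm = 8, step_rate = 0, omega_A0 = 1.53e-4,
                      omega_D = 0.25, omega_DC = 0.25, n_lanes = 1)
  cfg <- lattice_config(8, 400, concentration = 400, conc_unit = "nM",
                        burn_in_s = 40, seed = 3)
  s <- summarize_traffic(simulate_traffic(p, cfg))
  k <- 1.53e-4 * nM_to_per_um3(400)
  occ <- s$density_per_um / 125          # sites per um at 8 nm spacing
  expect_lt(abs(occ - k / (k + 0.25)), 3 * s$density_se / 125)
})

test_that("velocity decreases monotonically with concentration", {
  p <- table1_params()
  v <- vapply(c(20, 100, 400, 1200, 3000), function(cc) {
    cfg <- lattice_config(4, 60, concentration = cc, conc_unit = "nM",
                          burn_in_s = 20, seed = 31)
    ensemble_velocity(simulate_traffic(p, cfg))$velocity_um_s
  }, numeric(1))
  expect_true(all(diff(v) < 0))
})
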