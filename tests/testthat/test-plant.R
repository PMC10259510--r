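test_that("piezo actuation maps voltage to displacement with drift statistics", {
  pz <- piezo_model(gain = 0.5, voltage_range = c(-20, 20), drift_rate = 0,
                    gap_um = 50, coefficient_pF_um = 500)
  expect_identical(piezo_displacement(0, pz, dt = 0.1)$position, 0)
  expect_equal(piezo_displacement(10, pz, dt = 0.1)$position, 5)
  expect_false(piezo_displacement(10, pz, dt = 0.1)$saturated)
  out <- piezo_displacement(50, pz, dt = 0.1)
  expect_true(out$saturated)
  expect_equal(out$voltage, 20)

  # drift increments: sample variance ~ drift_rate^2 * dt within 20 %
  pzd <- piezo_model(gain = 0.5, voltage_range = c(-20, 20), drift_rate = 0.05,
                     gap_um = 50, coefficient_pF_um = 500)
  dt <- 0.25
  inc <- with_seed(42, {
    drift <- 0
    vapply(1:1000, function(i) {
      res <- piezo_displacement(0, pzd, drift = drift, dt = dt)
      d <- res$drift - drift
      drift <<- res$drift
      d
    }, numeric(1))
  })
  expect_lt(abs(stats::var(inc) / (pzd$drift_rate^2 * dt) - 1), 0.2)
})

test_that("capacitance pair follows the plate law and inverts exactly", {
  pz <- piezo_model(gain = 0.5, voltage_range = c(-20, 20), drift_rate = 0,
                    readout_noise_pF = 0, gap_um = 50, coefficient_pF_um = 100)
  c0 <- capacitance_pair(0, pz)
  expect_equal(unname(c0[1] - c0[2]), 0) # symmetry at centre
  cp <- capacitance_pair(10, pz)
  expect_equal(unname(cp[["C1"]]), 2.5)
  expect_equal(unname(cp[["C2"]]), 100 / 60)
  # antisymmetry of the difference
  cm <- capacitance_pair(-10, pz)
  expect_equal(unname(cp[["C1"]] - cp[["C2"]]),
               -unname(cm[["C1"]] - cm[["C2"]]))
  # exact inversion to 1e-9 um across the travel
  for (x in c(-35, -7.3, 0, 0.02, 21.9, 40)) {
    cc <- capacitance_pair(x, pz)
    expect_lt(abs(capacitance_difference_to_position(
      cc[["C1"]] - cc[["C2"]], pz) - x), 1e-9)
  }
  expect_error(capacitance_pair(50, pz), "plates touching")
})

test_that("force-velocity law stalls, runs free, and accelerates when assisted", {
  tis <- tissue_model(active_stress_Pa = 100, free_velocity_um_h = 150)
  expect_equal(tissue_velocity(100, tis), 0)        # stall definition
  expect_equal(tissue_velocity(0, tis), 150)        # free elongation
  expect_equal(tissue_velocity(50, tis), 75)        # half load
  expect_gt(tissue_velocity(-50, tis), 150)         # assisting load
  dead <- tissue_model(active_stress_Pa = 0, free_velocity_um_h = 150)
  expect_equal(tissue_velocity(50, dead), 0)        # fully dissipated
  # finite passive viscosity lets an over-stressed front retreat
  soft <- tissue_model(100, 150, passive_viscous = 0.5)
  expect_lt(tissue_velocity(150, soft), 0)
})

test_that("plant converges to the stall fixed point sigma_a0 * A / k", {
  pl <- stall_plant()
  sim <- simulate_plant(pl, 0, duration_s = 2 * 3600, dt = 2,
                        record_every_s = 300)
  defl <- sim$trajectory$X_T_true_um - sim$trajectory$X_C_true_um
  expect_lt(abs(tail(defl, 1) - 20) / 20, 0.01)
  # monotone approach with non-increasing increments
  expect_true(all(diff(defl) >= -1e-12))
  inc <- diff(sim$trajectory$X_T_true_um)
  expect_true(all(diff(inc) <= 1e-9))
})

test_that("a static plant stays static and active stress decays on schedule", {
  pl <- plant_init(foil_probe(), quiet_piezo(), tissue_model(100, 0),
                   contact_area_um2 = 4e4)
  sim <- simulate_plant(pl, 0, duration_s = 600, dt = 1)
  expect_true(all(sim$trajectory$X_T_true_um == 0))
  expect_true(all(sim$trajectory$X_C_true_um == 0))

  tau_h <- 2
  pl2 <- stall_plant(dissipation_h = tau_h)
  sim2 <- simulate_plant(pl2, 0, duration_s = 3 * 3600, dt = 5,
                         record_every_s = 600)
  expected <- 100 * exp(-sim2$trajectory$time_s / (tau_h * 3600))
  expect_true(all(abs(sim2$trajectory$sigma_a_Pa - expected) /
                    expected < 0.01))
})

test_that("deflection beyond the beam-theory regime is flagged", {
  pl <- plant_init(probe_spec(0.001, probe_length = 20), quiet_piezo(),
                   tissue_model(500, 3000), contact_area_um2 = 4e4)
  for (i in 1:500) pl <- step_plant(pl, 0, dt = 10)
  expect_true("beam_theory_exceeded" %in% pl$flags)
})

test_that("cell density is conserved under advection with a blocking foil", {
  dens <- list(x = seq(2.5, 197.5, by = 5), rho = rep(1, 40))
  pl <- stall_plant(piezo = quiet_piezo(), density_grid = dens,
                    tip_offset_um = 60)
  sim <- simulate_plant(pl, 30, duration_s = 3600, dt = 2,
                        record_every_s = 600, keep_density = TRUE)
  totals <- vapply(sim$density_snapshots, function(d) sum(d$rho), numeric(1))
  expect_true(all(abs(totals - totals[1]) / totals[1] < 1e-6))
  # mass piles up just upstream of the foil and thins downstream
  last <- sim$density_snapshots[[length(sim$density_snapshots)]]
  foil_x <- sim$state$X_T_true_um
  up <- last$x < foil_x & last$x > foil_x - 15
  down <- last$x > foil_x & last$x < foil_x + 15
  expect_gt(max(last$rho[up]), 1.2)
  expect_lt(min(last$rho[down]), 0.8)
})

test_that("sensor stream export carries the documented columns", {
  pl <- stall_plant()
  sim <- simulate_plant(pl, 0, duration_s = 60, dt = 1)
  path <- tempfile(fileext = ".csv")
  write_plant_trajectory(sim$trajectory, path)
  got <- utils::read.csv(path)
  expect_named(got, c("time_s", "X_C_true_um", "X_T_true_um", "C1_pF",
                      "C2_pF", "voltage_V", "sigma_a_Pa", "tissue_front_um"))
})

test_that("synthetic cell tracks are seeded, baseline-exact, and load-sensitive", {
  expect_identical(generate_cell_tracks(n_cells = 4, rng_seed = 7),
                   generate_cell_tracks(n_cells = 4, rng_seed = 7))
  # noise off: lateral speed equals the configured baseline exactly
  flow <- cell_flow_config(noise_sd_um = 0)
  tr <- generate_cell_tracks(flow, n_cells = 3, load_nN = 0,
                             duration_s = 3600, rng_seed = 3)
  sp <- interval_speeds(tr)
  expect_equal(unique(round(sp$speed_um_h, 9)), flow$lateral_base_um_h)
  # loaded cohort strictly more lateral on average
  s0 <- interval_speeds(generate_cell_tracks(n_cells = 100, load_nN = 0,
                                             rng_seed = 11))
  s1 <- interval_speeds(generate_cell_tracks(n_cells = 100, load_nN = 175,
                                             rng_seed = 12, label = "loaded"))
  expect_gt(mean(s1$speed_um_h), mean(s0$speed_um_h))
})
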