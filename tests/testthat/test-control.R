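make_table <- function(piezo, seed = 301) {
  free <- plant_init(sharp_probe(), piezo, contact = FALSE)
  sweep_calibration(free, seq(-70, 70, length.out = 25), rng_seed = seed)
}

test_that("holding against a quiet tissue measures no force and no stall", {
  piezo <- quiet_piezo()
  tab <- make_table(piezo)
  plant <- plant_init(foil_probe(), piezo, tissue_model(100, 0),
                      contact_area_um2 = 4e4)
  cfg <- control_config("hold_position", piezo, inner_rate_hz = 2,
                        imaging_rate_hz = 1 / 15, tracking_noise_um = 0.05)
  rec <- run_stall_measurement(plant, tab, duration_s = 1800, config = cfg,
                               rng_seed = 5)
  expect_lt(abs(mean(rec$F_nN)), 5)
  expect_null(attr(rec, "events")$stall_detected_s)
})

test_that("noise-free stall run converges to the fixed-point stress", {
  piezo <- quiet_piezo()
  tab <- make_table(piezo)
  plant <- plant_init(foil_probe(), piezo, tissue_model(100, 150),
                      contact_area_um2 = 4e4)
  cfg <- control_config("hold_position", piezo, inner_rate_hz = 1,
                        imaging_rate_hz = 1 / 30, tracking_noise_um = 0)
  rec <- run_stall_measurement(plant, tab, duration_s = 5400, config = cfg,
                               rng_seed = 1)
  expect_lt(abs(tail(rec$sigma_Pa, 1) - 100) / 100, 0.01)
  expect_false(is.null(attr(rec, "events")$stall_detected_s))
})

test_that("the chip holds its position against drift during a measurement", {
  piezo <- piezo_model() # drift on
  tab <- make_table(piezo)
  plant <- plant_init(foil_probe(), piezo, tissue_model(100, 150),
                      contact_area_um2 = 4e4)
  cfg <- control_config("hold_position", piezo, inner_rate_hz = 2,
                        imaging_rate_hz = 1 / 15, tracking_noise_um = 0.1)
  rec <- run_stall_measurement(plant, tab, duration_s = 3600, config = cfg,
                               rng_seed = 17)
  expect_lt(stats::sd(rec$X_C_est_um), cfg$settling_tolerance_um)
})

test_that("constant-force loading reaches and re-tracks its target", {
  piezo <- piezo_model()
  tab <- make_table(piezo)
  mk_plant <- function() plant_init(probe_spec(0.2), piezo,
                                    tissue_model(100, 150),
                                    contact_area_um2 = 2000)
  cfg <- control_config("constant_force", piezo, inner_rate_hz = 5,
                        imaging_rate_hz = 1, tracking_noise_um = 0.02,
                        settle_time_s = 120)
  # zero-force control: chip shadows the tip
  rec0 <- run_constant_force(mk_plant(), tab, 0, duration_s = 400,
                             config = cfg, rng_seed = 2)
  expect_lt(abs(settled_mean(rec0, "F_nN")), 1)
  # 175 nN target held within 5 % after settling (3 seeds)
  for (s in 1:3) {
    rec <- run_constant_force(mk_plant(), tab, 175, duration_s = 600,
                              config = cfg, rng_seed = s)
    expect_lt(abs(abs(settled_mean(rec, "F_nN")) - 175) / 175, 0.05)
  }
  # step change settles to the new value within the settling time
  sched <- function(t) if (t < 300) 100 else 200
  rec_s <- run_constant_force(mk_plant(), tab, sched, duration_s = 540,
                              config = cfg, rng_seed = 4)
  late <- rec_s$F_nN[rec_s$time_s > 300 + cfg$settle_time_s]
  expect_lt(abs(abs(mean(late)) - 200) / 200, 0.05)
})

test_that("every record row satisfies F = k * deflection and sigma = F / A", {
  piezo <- piezo_model()
  tab <- make_table(piezo)
  plant <- plant_init(foil_probe(), piezo, tissue_model(100, 150),
                      contact_area_um2 = 4e4)
  cfg <- control_config("hold_position", piezo, inner_rate_hz = 2,
                        imaging_rate_hz = 1 / 10, tracking_noise_um = 0.1)
  rec <- run_stall_measurement(plant, tab, duration_s = 1200, config = cfg,
                               rng_seed = 3)
  k <- attr(rec, "spring_constant")
  A <- attr(rec, "contact_area_um2")
  expect_equal(rec$F_nN, 1000 * k * rec$deflection_um, tolerance = 1e-12)
  expect_equal(rec$sigma_Pa, 1000 * rec$F_nN / A, tolerance = 1e-12)
  expect_equal(rec$deflection_um, rec$X_T_meas_um - rec$X_C_est_um,
               tolerance = 1e-12)
})

test_that("voltage saturation is logged and control keeps running at the rail", {
  piezo <- piezo_model()
  tab <- make_table(piezo)
  plant <- plant_init(foil_probe(), piezo, tissue_model(100, 150),
                      contact_area_um2 = 4e4)
  cfg <- control_config("hold_position", piezo, inner_rate_hz = 2,
                        imaging_rate_hz = 1 / 10, tracking_noise_um = 0.1,
                        voltage_limits = c(-0.02, 0.02))
  rec <- run_stall_measurement(plant, tab, duration_s = 900, config = cfg,
                               rng_seed = 6)
  expect_true(isTRUE(attr(rec, "events")$voltage_saturated))
  expect_equal(nrow(rec), 90L) # run completed despite the rail
})

test_that("experiment records round-trip through CSV with their sidecar", {
  piezo <- quiet_piezo()
  tab <- make_table(piezo)
  plant <- plant_init(foil_probe(), piezo, tissue_model(100, 150),
                      contact_area_um2 = 4e4)
  cfg <- control_config("hold_position", piezo, inner_rate_hz = 1,
                        imaging_rate_hz = 1 / 60, tracking_noise_um = 0)
  rec <- run_stall_measurement(plant, tab, duration_s = 1200, config = cfg,
                               rng_seed = 8)
  path <- tempfile(fileext = ".csv")
  write_experiment_record(rec, path)
  back <- read_experiment_record(path)
  for (col in names(rec)) {
    expect_equal(back[[col]], rec[[col]], tolerance = 1e-9)
  }
  expect_equal(attr(back, "spring_constant"), 0.2)
  expect_equal(attr(back, "contact_area_um2"), 4e4)
})
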