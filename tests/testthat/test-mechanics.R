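test_that("deflection-to-force and force-to-stress arithmetic is exact", {
  expect_identical(force_from_deflection(0.2, 5, 5), 0)
  expect_equal(force_from_deflection(0.01, 10, 0), 100)
  expect_equal(force_from_deflection(0.2, 20, 0), 4000)
  expect_identical(stress_estimate(0, 500), 0)
  expect_error(stress_estimate(100, 0), "positive")
  # consistency against the direct unit oracle for random tuples
  set.seed(1)
  for (i in 1:1000) {
    k <- runif(1, 0.005, 0.5)
    xt <- runif(1, -50, 50); xc <- runif(1, -50, 50)
    A <- runif(1, 100, 5e4)
    expect_equal(stress_estimate(force_from_deflection(k, xt, xc), A),
                 1e6 * k * (xt - xc) / A, tolerance = 1e-12)
  }
})

test_that("contact area follows probe geometry, depth and angle", {
  foil <- foil_probe()
  a <- contact_area(foil, contact_geometry(200))
  expect_equal(as.numeric(a), 4e4)
  # tilting projects the area by cos(theta)
  a15 <- contact_area(foil, contact_geometry(200,
                                             insertion_angle_rad = 15 * pi / 180))
  expect_equal(as.numeric(a15) / as.numeric(a), cos(15 * pi / 180))
  # triangular tip: halve the depth, quarter the area
  tri <- probe_spec(0.01, tip_shape = "triangular", tip_width = 40)
  a1 <- contact_area(tri, contact_geometry(40, 0))
  a2 <- contact_area(tri, contact_geometry(20, 0))
  expect_equal(as.numeric(a2) / as.numeric(a1), 0.25)
  expect_error(contact_area(foil, contact_geometry(0)), "no tissue contact")
  # depth beyond the foil height clips with a note
  deep <- contact_area(foil, contact_geometry(350))
  expect_true(attr(deep, "clipped"))
  expect_equal(as.numeric(deep), 4e4)
})

test_that("the error budget bounds a well-made foil and flags a bare tip", {
  # pre-adjusted foil construct in a thin tissue: total under 20 %
  foil100 <- probe_spec(0.01, tip_shape = "foil", foil_width = 100,
                        foil_height = 80, foil_thickness = 15)
  geom <- contact_geometry(100, depth_uncertainty_um = 20,
                           insertion_angle_rad = 15 * pi / 180,
                           imaging_depth_um = 100)
  b <- uncertainty_budget(foil100, geom, tracking_rmse_um = 0.05,
                          force_nN = 100)
  expect_lte(b$total, 0.20)
  expect_false(b$order_of_magnitude_flag)
  expect_equal(b$off_axis_force_fraction, sin(15 * pi / 180))
  # bare triangular tip at D = 30 +/- 20 um: order-of-magnitude stress only
  tri <- probe_spec(0.01, tip_shape = "triangular", tip_width = 40)
  b2 <- uncertainty_budget(tri, contact_geometry(30), tracking_rmse_um = 0.05,
                           force_nN = 100)
  expect_true(b2$order_of_magnitude_flag)
  # all uncertainty sources off: total is zero
  b0 <- uncertainty_budget(foil100,
                           contact_geometry(80, depth_uncertainty_um = 0),
                           tracking_rmse_um = 0, force_nN = 100,
                           fabrication_frac = 0)
  expect_identical(b0$total, 0)
})

test_that("budget totals are monotone and quadrature never exceeds worst case", {
  foil <- foil_probe()
  base_geom <- contact_geometry(150, insertion_angle_rad = 0.1)
  base <- uncertainty_budget(foil, base_geom, 0.05, 500)
  # increasing any single component cannot decrease the total
  more_track <- uncertainty_budget(foil, base_geom, 0.2, 500)
  expect_gte(more_track$total, base$total)
  more_angle <- uncertainty_budget(
    foil, contact_geometry(150, insertion_angle_rad = 0.3), 0.05, 500)
  expect_gte(more_angle$total, base$total)
  set.seed(7)
  for (i in 1:20) {
    g <- contact_geometry(runif(1, 30, 190), runif(1, 0, 20),
                          runif(1, 0, 0.4))
    rmse <- runif(1, 0, 0.2)
    wc <- uncertainty_budget(foil, g, rmse, 200,
                             combination_rule = "worst_case")
    qd <- uncertainty_budget(foil, g, rmse, 200,
                             combination_rule = "quadrature")
    expect_lte(qd$total, wc$total)
  }
  # vanishing angle and depth uncertainty recovers the fabrication-only budget
  lim <- uncertainty_budget(
    probe_spec(0.01, tip_shape = "foil", foil_width = 100, foil_height = 50,
               foil_thickness = 15),
    contact_geometry(60, depth_uncertainty_um = 0, insertion_angle_rad = 0),
    tracking_rmse_um = 0, force_nN = 100, fabrication_frac = 0.15)
  expect_equal(lim$total, 0.15)
})

test_that("zero force with finite tracking error is reported as unbounded", {
  b <- uncertainty_budget(foil_probe(), contact_geometry(150), 0.05, 0)
  expect_true(b$tracking_unbounded)
  expect_identical(unname(b$components["tracking"]), Inf)
})

test_that("a stress breakdown keeps sigma * A = F to machine precision", {
  geom <- contact_geometry(150, insertion_angle_rad = 0.1)
  sb <- stress_breakdown(320, foil_probe(), geom, tracking_rmse_um = 0.05)
  expect_equal(sb$sigma_Pa * sb$area_um2, 1000 * sb$force_nN,
               tolerance = 1e-12)
})
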