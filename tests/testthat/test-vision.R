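test_that("noise-free frames localize to a tenth of a pixel, both methods", {
  opt <- clean_optics()
  x_true <- 30.22
  fr <- render_frame(x_true, sharp_probe(), opt)
  cen <- locate_tip(fr)
  expect_false(cen$lost)
  expect_lt(abs(cen$x_um - x_true) / opt$pixel_size_um, 0.1)

  tmpl <- extract_template(render_frame(30, sharp_probe(), opt), c(30, 32))
  tem <- locate_tip(fr, prior_um = c(30, 32), method = "template",
                    template = tmpl)
  expect_false(tem$lost)
  expect_lt(abs(tem$x_um - x_true) / opt$pixel_size_um, 0.1)
})

test_that("a blank frame gives a lost fix with zero confidence", {
  blank <- matrix(0.4, 64, 64)
  res <- locate_tip(blank, pixel_size_um = 0.5)
  expect_true(res$lost)
  expect_identical(res$confidence, 0)
  expect_true(is.na(res$x_um))
})

test_that("localization is shift-equivariant for both methods", {
  opt <- high_snr_optics()
  fr <- render_frame(30.2, sharp_probe(), opt, rng_seed = 5)
  shift_px <- 3L
  shifted <- fr
  # shift the pixel content right by exactly 3 columns
  shifted$pixels <- cbind(fr$pixels[, 1:shift_px],
                          fr$pixels[, 1:(ncol(fr$pixels) - shift_px)])
  base <- locate_tip(fr)
  moved <- locate_tip(shifted)
  expect_lt(abs((moved$x_um - base$x_um) / opt$pixel_size_um - shift_px), 0.05)

  tmpl <- extract_template(fr, c(30.2, 32))
  base_t <- locate_tip(fr, prior_um = c(30.2, 32), method = "template",
                       template = tmpl)
  moved_t <- locate_tip(shifted, prior_um = c(31.7, 32), method = "template",
                        template = tmpl)
  expect_lt(abs((moved_t$x_um - base_t$x_um) / opt$pixel_size_um - shift_px),
            0.05)
})

test_that("sub-pixel localization is unbiased at high SNR and degrades gracefully", {
  probe <- sharp_probe()
  err_at <- function(opt, n, seed0) {
    vapply(seq_len(n), function(i) {
      x <- with_seed(seed0 + i, stats::runif(1, 25, 40))
      fr <- render_frame(x, probe, opt, rng_seed = seed0 + 1000 + i)
      (locate_tip(fr)$x_um - x) / opt$pixel_size_um
    }, numeric(1))
  }
  e <- err_at(high_snr_optics(), 80, 400)
  expect_lt(abs(mean(e)), 0.02)
  expect_lt(sqrt(mean(e^2)), 0.2)
  # RMSE non-decreasing as imaging depth (blur) grows
  rmse <- vapply(c(10, 100, 250), function(d) {
    sqrt(mean(err_at(optics_config(fov_px = c(128L, 128L),
                                   imaging_depth_um = d), 30, 700)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) >= 0))
})

test_that("tracking follows a moving tip and bridges short dropouts", {
  opt <- high_snr_optics()
  # constant velocity: slope recovered within 1 %
  v_um_s <- 0.05
  traj <- data.frame(time_s = seq(0, 145, by = 5),
                     X_T_true_um = 22 + v_um_s * seq(0, 145, by = 5))
  mov <- render_movie(traj, sharp_probe(), opt, rng_seed = 21)
  tr <- track_movie(mov, initial_um = 22)
  expect_false(attr(tr, "quality_fail"))
  fit <- stats::lm(x_um ~ time_s, data = tr[!tr$lost, ])
  expect_lt(abs(stats::coef(fit)[2] - v_um_s) / v_um_s, 0.01)

  # stationary, noise-free: trace jitter under 0.05 px
  still <- data.frame(time_s = 0:9, X_T_true_um = rep(27.4, 10))
  mov2 <- render_movie(still, sharp_probe(), clean_optics())
  tr2 <- track_movie(mov2, initial_um = 27)
  expect_lt(stats::sd(tr2$x_um) / opt$pixel_size_um, 0.05)

  # a two-frame dropout is bridged, not lost
  mov3 <- mov
  for (i in 7:8) mov3$frames[[i]]$pixels <- matrix(0.45, 128, 128)
  tr3 <- track_movie(mov3, initial_um = 22)
  expect_true(all(tr3$bridged[7:8]))
  expect_false(any(tr3$lost))
  expect_false(attr(tr3, "quality_fail"))

  # losing most frames raises the quality flag
  mov4 <- mov
  for (i in 5:30) mov4$frames[[i]]$pixels <- matrix(0.45, 128, 128)
  tr4 <- track_movie(mov4, initial_um = 22)
  expect_true(attr(tr4, "quality_fail"))
})

test_that("ROI mean intensity reports constants, single pixels, and errors", {
  still <- data.frame(time_s = 0:3, X_T_true_um = rep(25, 4))
  mov <- render_movie(still, sharp_probe(), clean_optics())
  tr <- roi_mean_intensity(mov, list(x_um = 50, y_um = 50, w_um = 8, h_um = 8))
  expect_equal(length(unique(tr$intensity)), 1L) # constant movie
  one <- roi_mean_intensity(mov, list(x_um = 10.25, y_um = 10.25,
                                      w_um = 0.4, h_um = 0.4))
  expect_equal(one$intensity[1], mov$frames[[1]]$pixels[21, 21])
  expect_error(roi_mean_intensity(mov, list(x_um = 500, y_um = 500,
                                            w_um = 2, h_um = 2)), "no pixels")
})

test_that("cells accumulating against the foil show up in the ROI traces", {
  dens <- list(x = seq(2.5, 197.5, by = 5), rho = rep(1, 40))
  pl <- stall_plant(density_grid = dens, tip_offset_um = 60)
  sim <- simulate_plant(pl, 30, duration_s = 3600, dt = 2,
                        record_every_s = 360, keep_density = TRUE)
  opt <- optics_config(fov_px = c(256L, 128L), channel = "fluorescent",
                       background_level = 0.1, texture_amplitude = 0,
                       read_noise_sd = 0, shot_noise_scale = 0)
  mov <- render_movie(sim$trajectory, foil_probe(), opt,
                      density_snapshots = sim$density_snapshots,
                      density_contrast = 0.15)
  anterior <- roi_mean_intensity(mov, list(x_um = 65, y_um = 32,
                                           w_um = 40, h_um = 40))
  posterior <- roi_mean_intensity(mov, list(x_um = 100, y_um = 32,
                                            w_um = 30, h_um = 40))
  expect_true(all(diff(anterior$intensity) >= -1e-9))
  expect_true(all(diff(posterior$intensity) <= 1e-9))
  expect_gt(tail(anterior$intensity, 1), anterior$intensity[1])
  expect_lt(tail(posterior$intensity, 1), posterior$intensity[1])
})

test_that("interval speeds convert displacement per window to um/h", {
  # 12 um/h straight line along the lateral axis
  tr <- data.frame(t_s = seq(0, 3600, by = 300), x_um = 0,
                   y_um = seq(0, 12, by = 1))
  sp <- interval_speeds(tr)
  expect_true(all(abs(sp$speed_um_h - 12) < 1e-9))
  # 1 um per 5-min window -> 12 um/h
  tr2 <- data.frame(t_s = c(0, 300), x_um = c(0, 0), y_um = c(0, 1))
  expect_equal(interval_speeds(tr2)$speed_um_h, 12)
  # orthogonal motion projects to zero
  tr3 <- data.frame(t_s = seq(0, 3600, by = 300),
                    x_um = seq(0, 24, by = 2), y_um = 0)
  expect_true(all(interval_speeds(tr3)$speed_um_h == 0))
  # shorter than one window -> empty
  short <- data.frame(t_s = c(0, 60), x_um = c(0, 1), y_um = c(0, 1))
  expect_equal(nrow(interval_speeds(short, window_s = 300)), 0L)
})
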