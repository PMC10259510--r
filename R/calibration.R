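#' Calibrate the capacitance-to-position lookup table
#'
#' Drives the piezo across a voltage grid with no sample loaded, pairs the
#' averaged capacitance difference at each point with the imaged chip
#' position, and fits monotone (Hyman spline) interpolants in both
#' directions. The round-trip error is estimated by leave-one-out refits at
#' the interior support points.
#'
#' @param plant a `plant_state` with `contact = FALSE` (chip visible).
#' @param voltage_grid increasing voltages (V), at least 5.
#' @param frames_per_point capacitance readings and images averaged per grid
#'   point.
#' @param imaging_noise_um s.d. of a single imaged chip-position measurement
#'   (um).
#' @param settle_steps plant steps taken at each voltage before reading.
#' @param dt_s plant step (s).
#' @param rng_seed optional seed.
#' @return an object of class `calibration_table`: support `dC_pF`,
#'   `position_um`, interpolants, `valid_range_pF`, `rt_rmse_um`.
#' @export
sweep_calibration <- function(plant, voltage_grid, frames_per_point = 10,
                              imaging_noise_um = 0.02, settle_steps = 3L,
                              dt_s = 0.05, rng_seed = NULL) {
  stopifnot(inherits(plant, "plant_state"))
  if (plant$contact) {
    stop("calibration requires an unloaded plant (no sample in contact)",
         call. = FALSE)
  }
  if (length(voltage_grid) < 5L) {
    stop("insufficient support: the voltage grid needs at least 5 points",
         call. = FALSE)
  }
  with_seed(rng_seed, {
    n <- length(voltage_grid)
    dC <- pos <- numeric(n)
    for (i in seq_len(n)) {
      for (s in seq_len(settle_steps)) {
        plant <- step_plant(plant, voltage_grid[i], dt = dt_s)
      }
      cs <- replicate(frames_per_point, {
        cp <- capacitance_pair(plant$X_C_true_um, plant$piezo)
        cp[["C1"]] - cp[["C2"]]
      })
      imgs <- plant$X_C_true_um +
        if (imaging_noise_um > 0) stats::rnorm(frames_per_point, 0, imaging_noise_um) else 0
      dC[i] <- mean(cs)
      pos[i] <- mean(imgs)
    }
    if (any(diff(dC) <= 0)) {
      stop("calibration failure: averaged capacitance sweep is not monotone",
           call. = FALSE)
    }
    inv <- stats::splinefun(dC, pos, method = "hyman")
    fwd <- stats::splinefun(pos, dC, method = "hyman")
    # leave-one-out round-trip error at interior support points
    interior <- 2:(n - 1)
    loo_err <- vapply(interior, function(i) {
      f <- stats::splinefun(dC[-i], pos[-i], method = "hyman")
      f(dC[i]) - pos[i]
    }, numeric(1))
    structure(
      list(dC_pF = dC, position_um = pos,
           invert = inv, forward = fwd,
           valid_range_pF = range(dC),
           position_range_um = range(pos),
           rt_rmse_um = sqrt(mean(loo_err^2)),
           frames_per_point = frames_per_point),
      class = "calibration_table"
    )
  })
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf(
    "<calibration_table> %d points, dC in [%.3f, %.3f] pF, x in [%.2f, %.2f] um, LOO RMSE %.3g um\n",
    length(x$dC_pF), x$valid_range_pF[1], x$valid_range_pF[2],
    x$position_range_um[1], x$position_range_um[2], x$rt_rmse_um))
  invisible(x)
}

#' Chip position from a capacitance difference
#'
#' Interpolates within the calibrated range; extrapolation is refused.
#'
#' @param table a `calibration_table`.
#' @param dC_pF capacitance difference(s) (pF).
#' @return chip position(s) in um.
#' @export
chip_position_from_capacitance <- function(table, dC_pF) {
  stopifnot(inherits(table, "calibration_table"))
  vr <- table$valid_range_pF
  if (any(dC_pF < vr[1] | dC_pF > vr[2])) {
    stop(sprintf(
      "capacitance difference outside the calibrated range [%.4f, %.4f] pF; refusing to extrapolate",
      vr[1], vr[2]), call. = FALSE)
  }
  table$invert(dC_pF)
}

#' Capacitance setpoint for a target chip position
#'
#' Forward use of the lookup table by the controllers; refuses positions
#' outside the calibrated travel.
#'
#' @param table a `calibration_table`.
#' @param position_um target chip position(s) (um).
#' @return capacitance difference(s) in pF.
#' @export
capacitance_setpoint_for <- function(table, position_um) {
  stopifnot(inherits(table, "calibration_table"))
  pr <- table$position_range_um
  if (any(position_um < pr[1] | position_um > pr[2])) {
    stop(sprintf(
      "target position outside the calibrated travel [%.2f, %.2f] um",
      pr[1], pr[2]), call. = FALSE)
  }
  table$forward(position_um)
}

#' Holder stability tests in three modes
#'
#' Reproduces the pre-experiment checks: (1) voltage controller off (tests
#' the scaffold; the voltage trace is identically zero), (2) voltage on at a
#' constant setting (exposes piezo drift), (3) capacitance feedback on (the
#' loop corrects the drift). Reports the maximal excursion and s.d. of chip
#' position per mode.
#'
#' @param plant a `plant_state` with no sample loaded.
#' @param duration_s test duration per mode (s).
#' @param dt_s step (s).
#' @param control a [control_config()] used for mode 3 (defaults supplied).
#' @param rng_seed optional seed (each mode uses an independent substream).
#' @return list with `report` (data.frame: mode, max_excursion_um, sd_um,
#'   voltage_sd_V) and `pass` (mode 1 quiet, and mode 3 tighter than mode 2).
#' @export
stability_suite <- function(plant, duration_s = 120, dt_s = 0.1,
                            control = NULL, rng_seed = NULL) {
  stopifnot(inherits(plant, "plant_state"), !plant$contact)
  if (is.null(control)) control <- control_config(mode = "hold_position",
                                                  piezo = plant$piezo,
                                                  inner_rate_hz = 1 / dt_s)
  with_seed(rng_seed, {
    n <- ceiling(duration_s / dt_s)
    run_mode <- function(mode) {
      st <- plant
      x <- v <- numeric(n)
      if (mode == 3L) {
        dC_set <- st$C1_pF - st$C2_pF
        volt <- 0
        e_prev <- 0
      }
      for (i in seq_len(n)) {
        if (mode == 1L) {
          # controller unpowered: chip held by the scaffold alone
          x[i] <- 0
          v[i] <- 0
          next
        } else if (mode == 2L) {
          st <- step_plant(st, 0, dt = dt_s)
        } else {
          dC_meas <- st$C1_pF - st$C2_pF
          e <- dC_set - dC_meas
          volt <- volt + control$kp * (e - e_prev) + control$ki * e * dt_s
          e_prev <- e
          st <- step_plant(st, volt, dt = dt_s)
        }
        x[i] <- st$X_C_true_um
        v[i] <- st$voltage_V
      }
      c(max_excursion_um = max(abs(x - x[1])), sd_um = stats::sd(x),
        voltage_sd_V = stats::sd(v))
    }
    rep_mat <- t(vapply(1:3, run_mode, numeric(3)))
    report <- data.frame(mode = c("controller_off", "voltage_on", "feedback_on"),
                         rep_mat)
    pass <- report$sd_um[1] < 0.01 && report$sd_um[3] < report$sd_um[2]
    list(report = report, pass = pass)
  })
}

#' Align the probe insertion angle by simulated mounting-arm rotation
#'
#' Focuses alternately on the probe tip and base planes, localizes the probe
#' in each, and rotates the mounting arm to null the on-camera horizontal
#' displacement between the two focal planes. The residual
#' `sin(theta_I) = horizontal displacement / L` is returned; with a 200 um
#' probe at 0.5 um/px this reaches well below 0.05.
#'
#' @param probe a [probe_spec()].
#' @param optics an [optics_config()]; frames are rendered and localized with
#'   [locate_tip()] at each focal plane.
#' @param initial_sin_theta starting tilt as sin(theta_I).
#' @param max_iterations iteration cap.
#' @param tol_um stop once the measured horizontal displacement falls below
#'   this (defaults to twice the pixel-noise floor, 0.1 um at 0.5 um/px).
#' @param rng_seed optional seed.
#' @return list with `sin_theta` (achieved residual), `theta_rad` (true
#'   remaining tilt), `iterations`, `converged` (FALSE carries a warning
#'   flag: best achieved returned).
#' @export
align_insertion_angle <- function(probe, optics = optics_config(fov_px = c(96L, 96L)),
                                  initial_sin_theta = 0.3,
                                  max_iterations = 10L, tol_um = NULL,
                                  rng_seed = NULL) {
  stopifnot(inherits(probe, "probe_spec"))
  L <- probe$probe_length
  if (is.null(tol_um)) tol_um <- 0.2 * optics$pixel_size_um
  with_seed(rng_seed, {
    theta <- asin(min(max(initial_sin_theta, -1), 1))
    x_base <- optics$fov_px[1] * optics$pixel_size_um / 2
    measure_h <- function(theta) {
      # on-camera horizontal offset between tip-focus and base-focus views
      f_base <- render_frame(x_base, probe, optics)
      f_tip <- render_frame(x_base + L * sin(theta), probe, optics)
      lb <- locate_tip(f_base, prior_um = x_base)
      lt <- locate_tip(f_tip, prior_um = x_base + L * sin(theta))
      if (lb$lost || lt$lost) return(NA_real_)
      lt$x_um - lb$x_um
    }
    h <- measure_h(theta)
    it <- 0L
    while (it < max_iterations && is.finite(h) && abs(h) > tol_um) {
      correction <- asin(min(max(h / L, -1), 1))
      theta <- theta - correction
      h <- measure_h(theta)
      it <- it + 1L
    }
    converged <- is.finite(h) && abs(h) <= tol_um
    if (!converged) {
      warning("alignment did not converge within max_iterations; ",
              "returning best achieved residual")
    }
    list(sin_theta = abs(h) / L, theta_rad = theta,
         iterations = it, converged = converged)
  })
}
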