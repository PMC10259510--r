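#' Piezo actuation: commanded voltage to chip displacement
#'
#' Converts a controller voltage into a chip position, accumulating random-walk
#' drift. Voltages outside the admissible range are saturated (flagged, not an
#' error), mirroring a real voltage controller hitting its rails.
#'
#' @param voltage commanded voltage (V).
#' @param piezo a [piezo_model()].
#' @param drift current accumulated drift (um).
#' @param dt time step (s) over which a drift increment is drawn.
#' @param rng_seed optional seed for the drift increment.
#' @return list with `position` (um), `drift` (updated accumulated drift, um),
#'   `voltage` (the possibly saturated voltage actually applied) and
#'   `saturated` (logical).
#' @export
piezo_displacement <- function(voltage, piezo, drift = 0, dt = 0.1,
                               rng_seed = NULL) {
  stopifnot(inherits(piezo, "piezo_model"))
  stop_if_not_scalar(voltage, "voltage")
  stop_if_not_scalar(dt, "dt", positive = TRUE)
  vr <- piezo$voltage_range
  v_applied <- min(max(voltage, vr[1]), vr[2])
  saturated <- v_applied != voltage
  drift_new <- with_seed(rng_seed, {
    if (piezo$drift_rate > 0) {
      drift + stats::rnorm(1L, 0, piezo$drift_rate * sqrt(dt))
    } else {
      drift
    }
  })
  list(
    position = piezo$gain * v_applied + drift_new,
    drift = drift_new,
    voltage = v_applied,
    saturated = saturated
  )
}

#' Capacitive chip-position readout
#'
#' Parallel-plate pair flanking the piezo: `C1 = c0/(g0 - x)`,
#' `C2 = c0/(g0 + x)`, plus independent Gaussian readout noise. The
#' difference `C1 - C2 = 2 c0 x / (g0^2 - x^2)` is strictly increasing and
#' antisymmetric in `x` on `|x| < g0`.
#'
#' @param chip_position chip position x (um); must satisfy `|x| < g0`.
#' @param piezo a [piezo_model()].
#' @param rng_seed optional seed for the readout noise.
#' @return named numeric vector `c(C1 = , C2 = )` in pF.
#' @export
capacitance_pair <- function(chip_position, piezo, rng_seed = NULL) {
  stopifnot(inherits(piezo, "piezo_model"))
  stop_if_not_scalar(chip_position, "chip_position")
  g0 <- piezo$gap_um
  if (abs(chip_position) >= g0) {
    stop(sprintf(
      "chip position %g um reaches the capacitor gap (g0 = %g um): plates touching",
      chip_position, g0), call. = FALSE)
  }
  c0 <- piezo$coefficient_pF_um
  clean <- c(C1 = c0 / (g0 - chip_position), C2 = c0 / (g0 + chip_position))
  if (piezo$readout_noise_pF > 0) {
    clean <- clean + with_seed(rng_seed,
                               stats::rnorm(2L, 0, piezo$readout_noise_pF))
  }
  clean
}

#' Exact inverse of the capacitance difference
#'
#' Analytic inversion of `dC = 2 c0 x / (g0^2 - x^2)` for `x`; the ground-truth
#' counterpart of the empirical lookup table built by [sweep_calibration()].
#'
#' @param dC capacitance difference C1 - C2 (pF); vectorized.
#' @param piezo a [piezo_model()].
#' @return chip position(s) in um.
#' @export
capacitance_difference_to_position <- function(dC, piezo) {
  stopifnot(inherits(piezo, "piezo_model"))
  g0 <- piezo$gap_um
  c0 <- piezo$coefficient_pF_um
  # dC * x^2 + 2 c0 x - dC g0^2 = 0, root with |x| < g0
  x <- ifelse(dC == 0, 0, (-c0 + sqrt(c0^2 + dC^2 * g0^2)) / dC)
  x
}

#' Force-velocity law of the active tissue front
#'
#' @param sigma_r resisting stress exerted by the probe on the front (Pa);
#'   negative values assist the front.
#' @param tissue a [tissue_model()]; its `active_stress_Pa` is the *current*
#'   capacity (pass the decayed value during simulation).
#' @return front velocity (um/h). Zero at stall (`sigma_r >= sigma_a` with
#'   infinite passive viscosity), `v0` when unloaded, above `v0` when
#'   assisted, negative (retreat) only when over-stressed with finite
#'   `passive_viscous`.
#' @export
tissue_velocity <- function(sigma_r, tissue) {
  stopifnot(inherits(tissue, "tissue_model"))
  sa <- tissue$active_stress_Pa
  v0 <- tissue$free_velocity_um_h
  if (sa <= 0) {
    v_active <- 0
  } else {
    v_active <- max(0, v0 * (1 - sigma_r / sa))
    if (sigma_r < 0) v_active <- v0 * (1 - sigma_r / sa) # assisted, > v0
  }
  v_passive <- 0
  if (is.finite(tissue$passive_viscous) && sigma_r > sa) {
    v_passive <- -(sigma_r - sa) / tissue$passive_viscous
  }
  v_active + v_passive
}

#' Initialize the ground-truth plant state
#'
#' Bundles instrument models with the dynamic state advanced by
#' [step_plant()]. With `contact = TRUE` the probe tip is pinned to the
#' tissue front (no slip); with `contact = FALSE` (e.g. during calibration)
#' the tip rigidly follows the chip.
#'
#' @param probe a [probe_spec()].
#' @param piezo a [piezo_model()].
#' @param tissue a [tissue_model()] (may be `NULL` when `contact = FALSE`).
#' @param contact_area_um2 tissue contact area A (um^2) used for the
#'   stress felt by the front.
#' @param contact logical; is the probe inserted and in contact?
#' @param tip_offset_um initial tip position (um); also the initial tissue
#'   front when in contact.
#' @param density_grid optional 1-D grid for a linear cell-density field:
#'   list with `x` (bin centres, um, uniform spacing) and `rho`
#'   (non-negative densities, cells/um).
#' @return an object of class `plant_state`.
#' @export
plant_init <- function(probe, piezo, tissue = NULL,
                       contact_area_um2 = NULL,
                       contact = TRUE,
                       tip_offset_um = 0,
                       density_grid = NULL) {
  stopifnot(inherits(probe, "probe_spec"), inherits(piezo, "piezo_model"))
  if (contact) {
    stopifnot(inherits(tissue, "tissue_model"))
    stop_if_not_scalar(contact_area_um2, "contact_area_um2", positive = TRUE)
  }
  if (!is.null(density_grid)) {
    stopifnot(is.list(density_grid), length(density_grid$x) > 2,
              length(density_grid$x) == length(density_grid$rho),
              all(density_grid$rho >= 0))
    dx <- diff(density_grid$x)
    stopifnot(all(abs(dx - dx[1]) < 1e-9))
  }
  state <- list(
    probe = probe, piezo = piezo, tissue = tissue,
    contact_area_um2 = contact_area_um2,
    contact = contact,
    time_s = 0,
    voltage_V = 0,
    drift_um = 0,
    X_C_true_um = 0,
    X_T_true_um = tip_offset_um,
    tissue_front_um = if (contact) tip_offset_um else NA_real_,
    sigma_a_Pa = if (contact) tissue$active_stress_Pa else NA_real_,
    C1_pF = NA_real_, C2_pF = NA_real_,
    density = density_grid,
    flags = character(0)
  )
  # store a noise-free initial reading
  g0 <- piezo$gap_um; c0 <- piezo$coefficient_pF_um
  state$C1_pF <- c0 / (g0 - state$X_C_true_um)
  state$C2_pF <- c0 / (g0 + state$X_C_true_um)
  class(state) <- "plant_state"
  state
}

#' @export
print.plant_state <- function(x, ...) {
  cat(sprintf(
    "<plant_state> t = %.1f s, X_C = %.3f um, X_T = %.3f um, sigma_a = %s Pa%s\n",
    x$time_s, x$X_C_true_um, x$X_T_true_um,
    ifelse(is.na(x$sigma_a_Pa), "NA", sprintf("%.2f", x$sigma_a_Pa)),
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

# conservative first-order upwind advection of the density field, flux blocked
# at the interface holding the foil and at both domain boundaries
advect_density <- function(density, foil_position_um, v_um_h, dt_s) {
  x <- density$x
  rho <- density$rho
  n <- length(rho)
  dx <- x[2] - x[1]
  c_um <- v_um_h * dt_s / 3600 # displacement this step, um
  if (c_um == 0) return(density)
  if (abs(c_um) > dx) {
    stop("advection CFL violated: reduce dt or coarsen the density grid",
         call. = FALSE)
  }
  # interfaces i + 1/2 at x[i] + dx/2, i = 1..n-1; zero flux at domain ends
  flux <- if (c_um > 0) c_um * rho[-n] else c_um * rho[-1]
  iface_pos <- x[-n] + dx / 2
  flux[abs(iface_pos - foil_position_um) <= dx / 2] <- 0 # foil blocks
  rho_new <- rho
  rho_new[-n] <- rho_new[-n] - flux / dx
  rho_new[-1] <- rho_new[-1] + flux / dx
  density$rho <- pmax(rho_new, 0)
  density
}

#' Advance the plant by one time step
#'
#' Couples the actuation path (voltage -> piezo -> chip position -> capacitor
#' readings) with the tissue: the resisting stress on the front is
#' `sigma_r = k (X_T - X_C) / A`, the front advances at [tissue_velocity()],
#' the pinned tip follows it, and the active capacity decays with the
#' dissipation timescale. An optional cell-density field is advected with the
#' front flow, with flux blocked at the foil.
#'
#' @param state a `plant_state`.
#' @param voltage_command commanded voltage (V).
#' @param dt time step (s).
#' @param rng_seed optional seed (drift + readout noise for this step).
#' @return the updated `plant_state`; `state$flags` gains
#'   `"voltage_saturated"` or `"beam_theory_exceeded"` when relevant.
#' @export
step_plant <- function(state, voltage_command, dt = 0.1, rng_seed = NULL) {
  stopifnot(inherits(state, "plant_state"))
  with_seed(rng_seed, {
    state$flags <- character(0)
    pz <- piezo_displacement(voltage_command, state$piezo,
                             drift = state$drift_um, dt = dt)
    if (pz$saturated) state$flags <- c(state$flags, "voltage_saturated")
    state$voltage_V <- pz$voltage
    state$drift_um <- pz$drift
    state$X_C_true_um <- pz$position

    if (state$contact) {
      k <- state$probe$spring_constant
      A <- state$contact_area_um2
      deflection <- state$X_T_true_um - state$X_C_true_um
      sigma_r <- Pa_from_deflection(k, deflection, A)
      tis <- state$tissue
      tis$active_stress_Pa <- state$sigma_a_Pa
      v <- tissue_velocity(sigma_r, tis)
      state$tissue_front_um <- state$tissue_front_um + v * dt / 3600
      state$X_T_true_um <- state$tissue_front_um # pinned, no slip
      if (is.finite(state$tissue$dissipation_h)) {
        state$sigma_a_Pa <- state$sigma_a_Pa *
          exp(-dt / (state$tissue$dissipation_h * 3600))
      }
      if (!is.null(state$density)) {
        state$density <- advect_density(state$density, state$X_T_true_um,
                                        v, dt)
      }
      if (abs(state$X_T_true_um - state$X_C_true_um) >
          0.5 * state$probe$probe_length) {
        state$flags <- c(state$flags, "beam_theory_exceeded")
      }
    } else {
      state$X_T_true_um <- state$X_C_true_um # rigid, no load
    }

    cp <- capacitance_pair(state$X_C_true_um, state$piezo)
    state$C1_pF <- cp[["C1"]]
    state$C2_pF <- cp[["C2"]]
    state$time_s <- state$time_s + dt
    state
  })
}

#' Simulate the plant under a voltage programme
#'
#' Open-loop convenience driver: steps the plant with a constant voltage or a
#' voltage function of time and records the trajectory.
#'
#' @param state a `plant_state`.
#' @param voltage scalar voltage or `function(t_s)` returning one.
#' @param duration_s total simulated time (s).
#' @param dt time step (s).
#' @param record_every_s trajectory sampling interval (s); defaults to `dt`.
#' @param rng_seed optional seed for the whole run.
#' @param keep_density logical, store density snapshots at sample times.
#' @return list with `trajectory` (data.frame with columns `time_s`,
#'   `X_C_true_um`, `X_T_true_um`, `C1_pF`, `C2_pF`, `voltage_V`,
#'   `sigma_a_Pa`, `tissue_front_um`), `state` (final plant state) and
#'   optionally `density_snapshots`.
#' @export
simulate_plant <- function(state, voltage = 0, duration_s, dt = 0.1,
                           record_every_s = dt, rng_seed = NULL,
                           keep_density = FALSE) {
  stopifnot(inherits(state, "plant_state"))
  stop_if_not_scalar(duration_s, "duration_s", positive = TRUE)
  v_fun <- if (is.function(voltage)) voltage else function(t) voltage
  n_steps <- ceiling(duration_s / dt)
  stride <- max(1L, round(record_every_s / dt))
  n_rec <- floor(n_steps / stride) + 1L
  rec <- matrix(NA_real_, nrow = n_rec, ncol = 8L)
  colnames(rec) <- c("time_s", "X_C_true_um", "X_T_true_um", "C1_pF",
                     "C2_pF", "voltage_V", "sigma_a_Pa", "tissue_front_um")
  snap <- function(s) c(s$time_s, s$X_C_true_um, s$X_T_true_um, s$C1_pF,
                        s$C2_pF, s$voltage_V, s$sigma_a_Pa, s$tissue_front_um)
  density_snaps <- if (keep_density) vector("list", n_rec) else NULL
  with_seed(rng_seed, {
    rec[1L, ] <- snap(state)
    if (keep_density) density_snaps[[1L]] <- state$density
    j <- 1L
    for (i in seq_len(n_steps)) {
      state <- step_plant(state, v_fun(state$time_s), dt = dt)
      if (i %% stride == 0L) {
        j <- j + 1L
        rec[j, ] <- snap(state)
        if (keep_density) density_snaps[[j]] <- state$density
      }
    }
    out <- list(trajectory = as.data.frame(rec[seq_len(j), , drop = FALSE]),
                state = state)
    if (keep_density) out$density_snapshots <- density_snaps[seq_len(j)]
    out
  })
}

#' Write a plant trajectory to CSV
#'
#' @param trajectory data.frame from [simulate_plant()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plant_trajectory <- function(trajectory, path) {
  needed <- c("time_s", "X_C_true_um", "X_T_true_um", "C1_pF", "C2_pF",
              "voltage_V", "sigma_a_Pa", "tissue_front_um")
  stopifnot(all(needed %in% names(trajectory)))
  utils::write.csv(trajectory[needed], path, row.names = FALSE)
  invisible(path)
}

#' Default U-shaped flow parameters for synthetic cell tracks
#'
#' Cells leave the posterior progenitor pool along U-shaped paths into the
#' paraxial mesoderm: an antero-posterior component that reverses sign over
#' the track, plus a steady medial-to-lateral component that grows with the
#' applied load.
#'
#' @param ap_amplitude_um_h amplitude of the AP velocity component (um/h).
#' @param lateral_base_um_h unloaded medial-to-lateral speed (um/h).
#' @param lateral_per_nN increase in lateral speed per nN of load (um/h/nN).
#' @param noise_sd_um per-interval isotropic positional noise s.d. (um).
#' @param interval_s sampling interval of the tracks (s).
#' @return list of flow parameters.
#' @export
cell_flow_config <- function(ap_amplitude_um_h = 30,
                             lateral_base_um_h = 6,
                             lateral_per_nN = 0.04,
                             noise_sd_um = 0.5,
                             interval_s = 300) {
  list(ap_amplitude_um_h = ap_amplitude_um_h,
       lateral_base_um_h = lateral_base_um_h,
       lateral_per_nN = lateral_per_nN,
       noise_sd_um = noise_sd_um,
       interval_s = interval_s)
}

#' Generate synthetic labelled-cell tracks under load
#'
#' Stand-in for dye-labelled cell clusters followed at 5-min intervals. The
#' mean medial-to-lateral speed component is
#' `lateral_base + lateral_per_nN * load_nN` exactly (a monotone
#' non-decreasing function of the load), with independent per-cell noise.
#'
#' @param flow a [cell_flow_config()].
#' @param n_cells number of cells (>= 1).
#' @param load_nN applied load (nN).
#' @param duration_s track duration (s).
#' @param rng_seed optional seed; the same seed and configuration reproduce
#'   the tracks exactly.
#' @param label `"loaded"` or `"control"` annotation.
#' @return data.frame with columns `cell_id`, `t_s`, `x_um` (AP axis),
#'   `y_um` (medial -> lateral positive), and attribute `label`.
#' @export
generate_cell_tracks <- function(flow = cell_flow_config(), n_cells,
                                 load_nN = 0, duration_s = 3600,
                                 rng_seed = NULL,
                                 label = c("control", "loaded")) {
  label <- match.arg(label)
  stopifnot(n_cells >= 1)
  dt <- flow$interval_s
  times <- seq(0, duration_s, by = dt)
  n_t <- length(times)
  v_lat <- flow$lateral_base_um_h + flow$lateral_per_nN * load_nN # um/h
  with_seed(rng_seed, {
    out <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      # per-cell progress phase through the U-turn
      phase <- stats::runif(1, 0, 1)
      s <- phase + (times / max(duration_s, dt)) * (1 - phase)
      v_ap <- -flow$ap_amplitude_um_h * cos(pi * s) # um/h, reverses sign
      dx <- v_ap[-n_t] * dt / 3600
      dy <- rep(v_lat * dt / 3600, n_t - 1L)
      if (flow$noise_sd_um > 0) {
        dx <- dx + stats::rnorm(n_t - 1L, 0, flow$noise_sd_um)
        dy <- dy + stats::rnorm(n_t - 1L, 0, flow$noise_sd_um)
      }
      out[[i]] <- data.frame(
        cell_id = i,
        t_s = times,
        x_um = cumsum(c(stats::runif(1, -50, 50), dx)),
        y_um = cumsum(c(stats::runif(1, 0, 30), dy))
      )
    }
    tracks <- do.call(rbind, out)
    attr(tracks, "label") <- label
    tracks
  })
}
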