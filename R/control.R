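#' Closed-loop controller configuration
#'
#' Two-rate architecture: a fast inner loop holds the capacitance difference
#' (chip position) with a velocity-form PI law on the piezo voltage, and a
#' slower imaging-rate outer loop updates the capacitance setpoint from the
#' tracked tip position during constant-force loading. Default gains are
#' derived from the piezo gain and the capacitor slope so the inner loop
#' corrects a set fraction of the error per step; anti-windup comes from the
#' velocity form plus voltage clamping.
#'
#' @param mode `"hold_position"` or `"constant_force"`.
#' @param piezo the [piezo_model()] the gains are scaled to.
#' @param setpoint target capacitance difference (pF, hold mode) or target
#'   force (nN, constant-force mode); may be set later by the runners.
#' @param kp proportional gain (V/pF); default from the loop-gain rule.
#' @param ki integral gain (V/(pF s)).
#' @param inner_rate_hz inner (capacitance) loop rate.
#' @param imaging_rate_hz outer (imaging) loop rate; camera-bound at 200 Hz.
#' @param voltage_limits length-2 (V); defaults to the piezo range.
#' @param settling_tolerance_um chip-position tolerance used in hold-quality
#'   reporting.
#' @param capacitance_filter_alpha exponential moving-average coefficient
#'   applied to the capacitance reading before the PI law (1 = no
#'   filtering); readout noise is high-rate, the dynamics hours-slow.
#' @param settle_time_s initial transient excluded from time averages.
#' @param tracking_noise_um s.d. of a single tip-position measurement when
#'   the imaging chain is emulated instead of rendered.
#' @param stall_window_s sliding window for stall detection.
#' @param stall_displacement_um stall criterion: displacement below this over
#'   the window.
#' @return an object of class `control_config`.
#' @export
control_config <- function(mode = c("hold_position", "constant_force"),
                           piezo = piezo_model(),
                           setpoint = NULL,
                           kp = NULL, ki = NULL,
                           inner_rate_hz = 100, imaging_rate_hz = 2,
                           voltage_limits = NULL,
                           settling_tolerance_um = 0.05,
                           capacitance_filter_alpha = 0.25,
                           settle_time_s = 60,
                           tracking_noise_um = 0.05,
                           stall_window_s = 600,
                           stall_displacement_um = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inner_rate_hz > 0, imaging_rate_hz > 0)
  if (imaging_rate_hz > 200) {
    stop("imaging-loop rate exceeds the 200 Hz camera bound", call. = FALSE)
  }
  if (is.null(voltage_limits)) voltage_limits <- piezo$voltage_range
  # capacitance slope at chip zero (pF/um); sets the loop gain scale
  slope <- 2 * piezo$coefficient_pF_um / piezo$gap_um^2
  dt <- 1 / inner_rate_hz
  if (is.null(ki)) ki <- 0.4 / (dt * piezo$gain * slope)
  if (is.null(kp)) kp <- 0.1 / (piezo$gain * slope)
  stopifnot(kp >= 0, ki >= 0)
  structure(
    list(mode = mode, setpoint = setpoint, kp = kp, ki = ki,
         inner_rate_hz = inner_rate_hz, imaging_rate_hz = imaging_rate_hz,
         voltage_limits = voltage_limits,
         settling_tolerance_um = settling_tolerance_um,
         capacitance_filter_alpha = capacitance_filter_alpha,
         settle_time_s = settle_time_s,
         tracking_noise_um = tracking_noise_um,
         stall_window_s = stall_window_s,
         stall_displacement_um = stall_displacement_um),
    class = "control_config"
  )
}

new_experiment_record <- function(rows, events, config, k, A, seed) {
  rec <- as.data.frame(rows)
  attr(rec, "events") <- events
  attr(rec, "config") <- config
  attr(rec, "spring_constant") <- k
  attr(rec, "contact_area_um2") <- A
  attr(rec, "seed") <- seed
  class(rec) <- c("experiment_record", "data.frame")
  rec
}

#' @export
print.experiment_record <- function(x, ...) {
  ev <- attr(x, "events")
  cat(sprintf("<experiment_record> %d rows, %.1f s; events: %s\n",
              nrow(x), max(x$time_s),
              if (length(ev)) paste(names(ev), collapse = ", ") else "none"))
  invisible(x)
}

# shared two-rate control loop; outer_update(t, X_T_meas, v_est) returns the
# new dC setpoint (or NULL to keep it)
run_control_loop <- function(plant, table, duration_s, config,
                             dC_set_init, outer_update, rng_seed,
                             events = list()) {
  dt <- 1 / config$inner_rate_hz
  img_every <- max(1L, round(config$inner_rate_hz / config$imaging_rate_hz))
  n <- ceiling(duration_s / dt)
  n_img <- floor(n / img_every)
  rows <- matrix(NA_real_, n_img, 8L)
  colnames(rows) <- c("time_s", "dC_pF", "voltage_V", "X_C_est_um",
                      "X_T_meas_um", "deflection_um", "F_nN", "sigma_Pa")
  k <- plant$probe$spring_constant
  A <- plant$contact_area_um2
  vlim <- config$voltage_limits
  with_seed(rng_seed, {
    volt <- plant$voltage_V
    e_prev <- 0
    dC_set <- dC_set_init
    alpha <- config$capacitance_filter_alpha
    dC_filt <- plant$C1_pF - plant$C2_pF
    X_T_prev <- NA_real_
    t_prev <- NA_real_
    v_est <- 0
    j <- 0L
    saturated_any <- FALSE
    for (i in seq_len(n)) {
      dC_meas <- plant$C1_pF - plant$C2_pF
      dC_filt <- (1 - alpha) * dC_filt + alpha * dC_meas
      e <- dC_set - dC_filt
      volt <- volt + config$kp * (e - e_prev) + config$ki * e * dt
      if (volt > vlim[2] || volt < vlim[1]) {
        volt <- min(max(volt, vlim[1]), vlim[2])
        saturated_any <- TRUE
      }
      e_prev <- e
      plant <- step_plant(plant, volt, dt = dt)
      if (i %% img_every == 0L) {
        j <- j + 1L
        X_T_meas <- plant$X_T_true_um +
          if (config$tracking_noise_um > 0)
            stats::rnorm(1L, 0, config$tracking_noise_um) else 0
        if (!is.na(X_T_prev)) {
          v_new <- (X_T_meas - X_T_prev) / (plant$time_s - t_prev)
          v_est <- 0.5 * v_est + 0.5 * v_new # um/s, lightly smoothed
        }
        X_T_prev <- X_T_meas
        t_prev <- plant$time_s
        dC_avg <- dC_filt # the instrument logs the filtered reading
        X_C_est <- chip_position_from_capacitance(
          table, min(max(dC_avg, table$valid_range_pF[1]),
                     table$valid_range_pF[2]))
        defl <- X_T_meas - X_C_est
        F_nN <- nN_from_deflection(k, defl)
        rows[j, ] <- c(plant$time_s, dC_avg, plant$voltage_V, X_C_est,
                       X_T_meas, defl, F_nN, Pa_from_force(F_nN, A))
        upd <- outer_update(plant$time_s, X_T_meas, v_est, defl)
        if (!is.null(upd)) dC_set <- upd
      }
    }
    if (saturated_any) events$voltage_saturated <- TRUE
    list(record = rows[seq_len(j), , drop = FALSE], plant = plant,
         events = events)
  })
}

# first time index at which displacement over the trailing window drops
# below the stall criterion
detect_stall <- function(time_s, x_um, window_s, disp_um) {
  for (i in seq_along(time_s)) {
    t0 <- time_s[i] - window_s
    if (t0 < time_s[1]) next
    sel <- time_s >= t0 & time_s <= time_s[i]
    if (diff(range(x_um[sel])) < disp_um) return(time_s[i])
  }
  NA_real_
}

#' Stall-stress measurement: hold the chip, watch the tip
#'
#' The inner loop pins the capacitance difference (chip position) at its
#' initial value while the advancing tissue deflects the cantilever; the
#' imaging loop tracks the tip. The record carries deflection, force and
#' stress over time (`F = k * deflection`, `sigma = F / A` exactly, per
#' row), and a stall event is logged once the tip displacement over a
#' sliding window falls below the criterion.
#'
#' @param plant a `plant_state` with the probe in contact.
#' @param table a `calibration_table`.
#' @param duration_s experiment duration (s).
#' @param config a [control_config()] (hold mode).
#' @param rng_seed optional seed.
#' @return an `experiment_record`.
#' @export
run_stall_measurement <- function(plant, table, duration_s,
                                  config = control_config("hold_position",
                                                          plant$piezo),
                                  rng_seed = NULL) {
  stopifnot(inherits(plant, "plant_state"), plant$contact,
            inherits(table, "calibration_table"))
  dC0 <- plant$C1_pF - plant$C2_pF
  res <- run_control_loop(plant, table, duration_s, config,
                          dC_set_init = dC0,
                          outer_update = function(t, xt, v, d) NULL,
                          rng_seed = rng_seed,
                          events = list(insertion_s = 0))
  rec <- res$record
  events <- res$events
  st <- detect_stall(rec[, "time_s"], rec[, "X_T_meas_um"],
                     config$stall_window_s, config$stall_displacement_um)
  # only meaningful once the tip has actually moved
  if (!is.na(st) && diff(range(rec[, "X_T_meas_um"])) >
      2 * config$stall_displacement_um) {
    events$stall_detected_s <- st
  }
  new_experiment_record(rec, events, config, plant$probe$spring_constant,
                        plant$contact_area_um2, rng_seed)
}

#' Constant-force loading via the imaging feedback loop
#'
#' The outer loop converts the force target into a deflection target
#' `delta* = F* / k`, predicts the tip position half an imaging period
#' ahead from its tracked velocity, and moves the capacitance setpoint so
#' the chip shadows the tip at the target deflection; the inner loop holds
#' that setpoint. Positive `direction = "oppose"` resists the tissue's
#' advance; `"assist"` (the loading experiment) pulls along it.
#'
#' @param plant a `plant_state` with the probe in contact.
#' @param table a `calibration_table`.
#' @param F_target_nN force magnitude target (nN), or a `function(t_s)`
#'   returning one (step protocols).
#' @param duration_s run time (s).
#' @param config a [control_config()].
#' @param direction `"assist"` or `"oppose"`.
#' @param rng_seed optional seed.
#' @return an `experiment_record`; saturation of the voltage or of the
#'   calibrated travel is logged in its events.
#' @export
run_constant_force <- function(plant, table, F_target_nN, duration_s,
                               config = control_config("constant_force",
                                                       plant$piezo),
                               direction = c("assist", "oppose"),
                               rng_seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(plant, "plant_state"), plant$contact,
            inherits(table, "calibration_table"))
  k <- plant$probe$spring_constant
  f_fun <- if (is.function(F_target_nN)) F_target_nN else function(t) F_target_nN
  sgn <- if (direction == "assist") -1 else 1
  img_period <- 1 / config$imaging_rate_hz
  pr <- table$position_range_um
  travel_saturated <- FALSE
  trim_um <- 0 # outer integral action on the measured deflection error
  started <- FALSE
  outer <- function(t, X_T_meas, v_est, defl_meas) {
    delta_star <- sgn * f_fun(t) / (1000 * k)
    if (started) trim_um <<- trim_um + 0.3 * (defl_meas - delta_star)
    started <<- TRUE
    x_target <- (X_T_meas + v_est * img_period / 2) - delta_star + trim_um
    if (x_target < pr[1] || x_target > pr[2]) {
      travel_saturated <<- TRUE
      x_target <- min(max(x_target, pr[1]), pr[2])
    }
    capacitance_setpoint_for(table, x_target)
  }
  dC0 <- plant$C1_pF - plant$C2_pF
  res <- run_control_loop(plant, table, duration_s, config,
                          dC_set_init = dC0, outer_update = outer,
                          rng_seed = rng_seed,
                          events = list(insertion_s = 0))
  events <- res$events
  if (travel_saturated) events$travel_saturated <- TRUE
  new_experiment_record(res$record, events, config, k,
                        plant$contact_area_um2, rng_seed)
}

#' Time-averaged value after the settling transient
#'
#' @param record an `experiment_record`.
#' @param column column to average.
#' @param settle_time_s transient to discard; defaults to the config's.
#' @return the mean of the column over the settled part.
#' @export
settled_mean <- function(record, column = "F_nN", settle_time_s = NULL) {
  cfg <- attr(record, "config")
  if (is.null(settle_time_s)) settle_time_s <- cfg$settle_time_s
  sel <- record$time_s > settle_time_s
  if (!any(sel)) stop("record shorter than the settling time", call. = FALSE)
  mean(record[[column]][sel])
}

#' Write an experiment record as CSV with a JSON sidecar
#'
#' @param record an `experiment_record`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json` (events, config snapshot, seed, k, A).
#' @return `path`, invisibly.
#' @export
write_experiment_record <- function(record, path) {
  stopifnot(inherits(record, "experiment_record"))
  utils::write.csv(as.data.frame(record), path, row.names = FALSE)
  side <- list(
    events = attr(record, "events"),
    config = unclass(attr(record, "config")),
    spring_constant_N_m = attr(record, "spring_constant"),
    contact_area_um2 = attr(record, "contact_area_um2"),
    seed = attr(record, "seed")
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an experiment record written by [write_experiment_record()]
#'
#' @param path the CSV path.
#' @return an `experiment_record`.
#' @export
read_experiment_record <- function(path) {
  rec <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    attr(rec, "events") <- side$events
    attr(rec, "config") <- side$config
    attr(rec, "spring_constant") <- side$spring_constant_N_m
    attr(rec, "contact_area_um2") <- side$contact_area_um2
    attr(rec, "seed") <- side$seed
  }
  class(rec) <- c("experiment_record", "data.frame")
  rec
}
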