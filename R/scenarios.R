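#' Built-in scenario presets
#'
#' Complete, seeded configurations for the three in-silico experiments:
#' \describe{
#'   \item{axial_stall}{stiff probe (k = 0.2 N/m) carrying a 200 um square
#'     foil blocks the elongating body axis; the chip is held and the tissue
#'     deflects the cantilever until it stalls (fixed-point stress 100 Pa
#'     over A = 4e4 um^2).}
#'   \item{ppsm_compression}{soft triangular probe (k = 0.01 N/m) loaded
#'     sideways by the converging paraxial mesoderm; the measured force
#'     stalls near 100 nN and dissipates over a couple of hours.}
#'   \item{constant_load}{fluorescent sharp tip applies a steady 175 nN
#'     assisting load (within the 150-200 nN loading range) through the
#'     imaging feedback loop; elongation roughly doubles.}
#' }
#'
#' @param name preset name.
#' @return an object of class `scenario_config` (nested named list, fully
#'   YAML-serializable, every stochastic component seeded).
#' @export
scenario_preset <- function(name = c("axial_stall", "ppsm_compression",
                                     "constant_load")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("axial_stall", "ppsm_compression", "constant_load")) {
    stop("unknown scenario; available presets: axial_stall, ",
         "ppsm_compression, constant_load", call. = FALSE)
  }
  piezo <- list(gain = 2, voltage_range = c(-75, 75), drift_rate = 0.02,
                readout_noise_pF = 0.004, gap_um = 200,
                coefficient_pF_um = 2000)
  calibration <- list(voltage_min = -70, voltage_max = 70, n_points = 25,
                      frames_per_point = 10, imaging_noise_um = 0.02)
  base <- switch(
    name,
    axial_stall = list(
      name = "axial_stall",
      probe = list(spring_constant = 0.2, probe_length = 200, tip_width = 30,
                   tip_thickness = 1, tip_shape = "foil", foil_width = 200,
                   foil_height = 200, foil_thickness = 15, label = "none"),
      tissue = list(active_stress_Pa = 100, free_velocity_um_h = 150,
                    dissipation_h = Inf, passive_viscous = Inf,
                    contact_mode = "blocking"),
      contact_area_um2 = 4e4,
      control = list(mode = "hold_position", inner_rate_hz = 1,
                     imaging_rate_hz = 1 / 30, tracking_noise_um = 0.1,
                     settle_time_s = 60, stall_window_s = 600,
                     stall_displacement_um = 0.5, F_target_nN = NA),
      analysis = list(initial_window_min = 30, rate_threshold_Pa_min = 0.5,
                      smooth_width = 9),
      duration_s = 9000
    ),
    ppsm_compression = list(
      name = "ppsm_compression",
      probe = list(spring_constant = 0.01, probe_length = 200, tip_width = 40,
                   tip_thickness = 1, tip_shape = "triangular",
                   foil_width = NA, foil_height = NA, foil_thickness = NA,
                   label = "none"),
      tissue = list(active_stress_Pa = 56, free_velocity_um_h = 15,
                    dissipation_h = 2, passive_viscous = 0.5,
                    contact_mode = "lateral"),
      contact_area_um2 = 3000,
      control = list(mode = "hold_position", inner_rate_hz = 0.5,
                     imaging_rate_hz = 1 / 60, tracking_noise_um = 0.05,
                     settle_time_s = 60, stall_window_s = 1800,
                     stall_displacement_um = 0.5, F_target_nN = NA),
      analysis = list(initial_window_min = 30, rate_threshold_Pa_min = 0.2,
                      smooth_width = 9),
      duration_s = 21600
    ),
    constant_load = list(
      name = "constant_load",
      probe = list(spring_constant = 0.2, probe_length = 200, tip_width = 30,
                   tip_thickness = 1, tip_shape = "sharp",
                   foil_width = NA, foil_height = NA, foil_thickness = NA,
                   label = "fluorescent"),
      tissue = list(active_stress_Pa = 100, free_velocity_um_h = 150,
                    dissipation_h = Inf, passive_viscous = Inf,
                    contact_mode = "blocking"),
      contact_area_um2 = 2000,
      control = list(mode = "constant_force", inner_rate_hz = 5,
                     imaging_rate_hz = 1, tracking_noise_um = 0.02,
                     settle_time_s = 120, stall_window_s = 600,
                     stall_displacement_um = 0.5, F_target_nN = 175),
      analysis = list(initial_window_min = 30, rate_threshold_Pa_min = 0.5,
                      smooth_width = 5),
      duration_s = 900
    )
  )
  cfg <- c(base["name"],
           list(probe = base$probe, piezo = piezo, tissue = base$tissue,
                contact_area_um2 = base$contact_area_um2,
                optics = list(pixel_size_um = 0.5, fov_px = c(128L, 128L),
                              imaging_depth_um = 30, blur_px_per_100um = 2,
                              channel = if (identical(base$probe$label,
                                                      "fluorescent"))
                                "fluorescent" else "brightfield"),
                calibration = calibration,
                control = base$control,
                analysis = base$analysis,
                duration_s = base$duration_s,
                seeds = list(calibration = 101, experiment = 202,
                             optics = 303)))
  class(cfg) <- "scenario_config"
  cfg
}

scenario_schema <- function() {
  list(
    top = c("name", "probe", "piezo", "tissue", "contact_area_um2", "optics",
            "calibration", "control", "analysis", "duration_s", "seeds"),
    probe = c("spring_constant", "probe_length", "tip_width", "tip_thickness",
              "tip_shape", "foil_width", "foil_height", "foil_thickness",
              "label"),
    piezo = c("gain", "voltage_range", "drift_rate", "readout_noise_pF",
              "gap_um", "coefficient_pF_um"),
    tissue = c("active_stress_Pa", "free_velocity_um_h", "dissipation_h",
               "passive_viscous", "contact_mode"),
    optics = c("pixel_size_um", "fov_px", "imaging_depth_um",
               "blur_px_per_100um", "channel"),
    calibration = c("voltage_min", "voltage_max", "n_points",
                    "frames_per_point", "imaging_noise_um"),
    control = c("mode", "inner_rate_hz", "imaging_rate_hz",
                "tracking_noise_um", "settle_time_s", "stall_window_s",
                "stall_displacement_um", "F_target_nN"),
    analysis = c("initial_window_min", "rate_threshold_Pa_min",
                 "smooth_width"),
    seeds = c("calibration", "experiment", "optics")
  )
}

#' Validate a scenario configuration against the schema
#'
#' Rejects missing or unexpected keys with a message naming them.
#'
#' @param cfg a scenario configuration list.
#' @return `cfg` (classed `scenario_config`), invisibly, or an error.
#' @export
validate_scenario <- function(cfg) {
  sch <- scenario_schema()
  check <- function(have, want, where) {
    missing <- setdiff(want, have)
    extra <- setdiff(have, want)
    if (length(missing)) {
      stop(sprintf("scenario config is missing key(s) %s in `%s`",
                   paste(missing, collapse = ", "), where), call. = FALSE)
    }
    if (length(extra)) {
      stop(sprintf("scenario config has unexpected key(s) %s in `%s`",
                   paste(extra, collapse = ", "), where), call. = FALSE)
    }
  }
  check(names(cfg), sch$top, "top level")
  for (sec in setdiff(sch$top, c("name", "contact_area_um2", "duration_s"))) {
    check(names(cfg[[sec]]), sch[[sec]], sec)
  }
  class(cfg) <- "scenario_config"
  invisible(cfg)
}

# canonical YAML text for a config (stable key order, stable number format)
scenario_yaml <- function(cfg) {
  yaml::as.yaml(unclass(cfg), precision = 12L)
}

#' Write / read scenario configurations as YAML
#'
#' The writer emits a canonical form: loading a file and saving it again is
#' byte-identical.
#'
#' @param cfg a `scenario_config`.
#' @param path YAML file path.
#' @return `path` (writer) or a validated `scenario_config` (reader).
#' @export
write_scenario <- function(cfg, path) {
  validate_scenario(cfg)
  writeLines(scenario_yaml(cfg), path, sep = "")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$tissue)) {
    for (f in c("dissipation_h", "passive_viscous")) {
      if (identical(cfg$tissue[[f]], ".inf")) cfg$tissue[[f]] <- Inf
    }
  }
  validate_scenario(cfg)
  cfg <- structure(cfg, class = "scenario_config")
  cfg
}

probe_from_config <- function(p) {
  foil <- identical(p$tip_shape, "foil")
  probe_spec(p$spring_constant, p$probe_length, p$tip_width, p$tip_thickness,
             p$tip_shape,
             foil_width = if (foil) p$foil_width,
             foil_height = if (foil) p$foil_height,
             foil_thickness = if (foil) p$foil_thickness,
             label = p$label)
}

piezo_from_config <- function(p) {
  piezo_model(p$gain, p$voltage_range, p$drift_rate, p$readout_noise_pF,
              p$gap_um, p$coefficient_pF_um)
}

tissue_from_config <- function(t) {
  tissue_model(t$active_stress_Pa, t$free_velocity_um_h, t$dissipation_h,
               t$passive_viscous, t$contact_mode)
}

control_from_config <- function(cc, piezo) {
  control_config(mode = cc$mode, piezo = piezo,
                 inner_rate_hz = cc$inner_rate_hz,
                 imaging_rate_hz = cc$imaging_rate_hz,
                 tracking_noise_um = cc$tracking_noise_um,
                 settle_time_s = cc$settle_time_s,
                 stall_window_s = cc$stall_window_s,
                 stall_displacement_um = cc$stall_displacement_um)
}

#' Run a full in-silico experiment from a scenario configuration
#'
#' Calibrates the capacitance lookup table, runs the configured protocol
#' (chip hold for stall measurement, or constant-force loading) and analyses
#' the resulting record.
#'
#' @param cfg a `scenario_config` (e.g. from [scenario_preset()]).
#' @param rng_seed optional integer overriding the config seeds (the
#'   calibration and experiment substreams are derived from it).
#' @param duration_s optional override of the configured duration.
#' @return list with `config`, `table` (calibration), `record`
#'   (`experiment_record`), `trace` (stress trace) and `metrics`
#'   ([stall_metrics()] result).
#' @export
run_scenario <- function(cfg, rng_seed = NULL, duration_s = NULL) {
  validate_scenario(cfg)
  probe <- probe_from_config(cfg$probe)
  piezo <- piezo_from_config(cfg$piezo)
  tissue <- tissue_from_config(cfg$tissue)
  seed_cal <- if (is.null(rng_seed)) cfg$seeds$calibration else rng_seed * 2L + 1L
  seed_exp <- if (is.null(rng_seed)) cfg$seeds$experiment else rng_seed * 2L + 2L
  if (is.null(duration_s)) duration_s <- cfg$duration_s

  free <- plant_init(probe, piezo, contact = FALSE)
  grid <- seq(cfg$calibration$voltage_min, cfg$calibration$voltage_max,
              length.out = cfg$calibration$n_points)
  table <- sweep_calibration(free, grid,
                             frames_per_point = cfg$calibration$frames_per_point,
                             imaging_noise_um = cfg$calibration$imaging_noise_um,
                             rng_seed = seed_cal)

  plant <- plant_init(probe, piezo, tissue,
                      contact_area_um2 = cfg$contact_area_um2)
  control <- control_from_config(cfg$control, piezo)
  record <- if (identical(cfg$control$mode, "constant_force")) {
    run_constant_force(plant, table, cfg$control$F_target_nN, duration_s,
                       config = control, rng_seed = seed_exp)
  } else {
    run_stall_measurement(plant, table, duration_s, config = control,
                          rng_seed = seed_exp)
  }
  tr <- stress_trace(record)
  metrics <- if (max(tr$time_s) / 60 > cfg$analysis$initial_window_min &&
                 identical(cfg$control$mode, "hold_position")) {
    stall_metrics(tr,
                  initial_window_min = cfg$analysis$initial_window_min,
                  rate_threshold_Pa_min = cfg$analysis$rate_threshold_Pa_min,
                  smooth_width = cfg$analysis$smooth_width)
  } else {
    NULL
  }
  list(config = cfg, table = table, record = record, trace = tr,
       metrics = metrics)
}

md5_of_text <- function(text) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(text, tf, sep = "")
  unname(tools::md5sum(tf))
}

#' Write a run manifest
#'
#' JSON manifest tying a completed run to its configuration: canonical
#' config hash, seeds, package version and checksums of the output files.
#'
#' @param config the `scenario_config` used.
#' @param files character vector of output file paths to checksum.
#' @param path manifest output path (JSON).
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(config, files, path) {
  stopifnot(all(file.exists(files)))
  manifest <- list(
    config_hash = md5_of_text(scenario_yaml(config)),
    seeds = config$seeds,
    package_version = as.character(utils::packageVersion("tifmtwin")),
    files = lapply(stats::setNames(as.list(files), basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname write_run_manifest
#' @export
read_run_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
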