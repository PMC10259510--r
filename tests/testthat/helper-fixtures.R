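# shared fixtures: probes, a noise-free piezo, and optics presets

foil_probe <- function(k = 0.2) {
  probe_spec(k, tip_shape = "foil",
             foil_width = 200, foil_height = 200, foil_thickness = 15)
}

sharp_probe <- function(k = 0.01, tip_width = 10) {
  probe_spec(k, tip_width = tip_width, tip_shape = "sharp")
}

quiet_piezo <- function(...) {
  piezo_model(drift_rate = 0, readout_noise_pF = 0, ...)
}

# high-SNR imaging: shallow depth, faint texture, low sensor noise
high_snr_optics <- function(fov_px = c(128L, 128L), ...) {
  optics_config(fov_px = fov_px, imaging_depth_um = 10,
                texture_amplitude = 0.004, read_noise_sd = 0.002,
                shot_noise_scale = 0.002, ...)
}

# completely clean imaging: no texture, no noise
clean_optics <- function(fov_px = c(128L, 128L), ...) {
  optics_config(fov_px = fov_px, texture_amplitude = 0,
                read_noise_sd = 0, shot_noise_scale = 0, ...)
}

# axial-stall plant at the fixed-point conditions (sigma_a0 * A / k = 20 um)
stall_plant <- function(piezo = quiet_piezo(), sigma_a0 = 100, v0 = 150,
                        dissipation_h = Inf, density_grid = NULL,
                        tip_offset_um = 0) {
  plant_init(foil_probe(), piezo,
             tissue_model(sigma_a0, v0, dissipation_h),
             contact_area_um2 = 4e4, tip_offset_um = tip_offset_um,
             density_grid = density_grid)
}
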