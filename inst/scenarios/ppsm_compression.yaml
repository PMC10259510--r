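name: ppsm_compression
probe:
  spring_constant: 0.01
  probe_length: 200.0
  tip_width: 40.0
  tip_thickness: 1.0
  tip_shape: triangular
  foil_width: .na
  foil_height: .na
  foil_thickness: .na
  label: none
piezo:
  gain: 2.0
  voltage_range:
  - -75.0
  - 75.0
  drift_rate: 0.02
  readout_noise_pF: 0.004
  gap_um: 200.0
  coefficient_pF_um: 2000.0
tissue:
  active_stress_Pa: 56.0
  free_velocity_um_h: 15.0
  dissipation_h: 2.0
  passive_viscous: 0.5
  contact_mode: lateral
contact_area_um2: 3000.0
optics:
  pixel_size_um: 0.5
  fov_px:
  - 128
  - 128
  imaging_depth_um: 30.0
  blur_px_per_100um: 2.0
  channel: brightfield
calibration:
  voltage_min: -70.0
  voltage_max: 70.0
  n_points: 25.0
  frames_per_point: 10.0
  imaging_noise_um: 0.02
control:
  mode: hold_position
  inner_rate_hz: 0.5
  imaging_rate_hz: 0.016666666667
  tracking_noise_um: 0.05
  settle_time_s: 60.0
  stall_window_s: 1800.0
  stall_displacement_um: 0.5
  F_target_nN: .na
analysis:
  initial_window_min: 30.0
  rate_threshold_Pa_min: 0.2
  smooth_width: 9.0
duration_s: 21600.0
seeds:
  calibration: 101.0
  experiment: 202.0
  optics: 303.0
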