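name: axial_stall
probe:
  spring_constant: 0.2
  probe_length: 200.0
  tip_width: 30.0
  tip_thickness: 1.0
  tip_shape: foil
  foil_width: 200.0
  foil_height: 200.0
  foil_thickness: 15.0
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
  active_stress_Pa: 100.0
  free_velocity_um_h: 150.0
  dissipation_h: .inf
  passive_viscous: .inf
  contact_mode: blocking
contact_area_um2: 40000.0
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
  inner_rate_hz: 1.0
  imaging_rate_hz: 0.033333333333
  tracking_noise_um: 0.1
  settle_time_s: 60.0
  stall_window_s: 600.0
  stall_displacement_um: 0.5
  F_target_nN: .na
analysis:
  initial_window_min: 30.0
  rate_threshold_Pa_min: 0.5
  smooth_width: 9.0
duration_s: 9000.0
seeds:
  calibration: 101.0
  experiment: 202.0
  optics: 303.0
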