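# File formats

All tabular outputs are CSV with a header row; configs are YAML; manifests
and summaries are JSON; movies are multi-page 16-bit TIFF.

## Plant trajectory CSV (`write_plant_trajectory`)

| column          | units | meaning                                   |
|-----------------|-------|-------------------------------------------|
| time_s          | s     | simulation time                            |
| X_C_true_um     | um    | ground-truth chip (holder) position        |
| X_T_true_um     | um    | ground-truth tip position                  |
| C1_pF, C2_pF    | pF    | capacitor pair readings (noise-free state) |
| voltage_V       | V     | applied piezo voltage                      |
| sigma_a_Pa      | Pa    | current active stress capacity             |
| tissue_front_um | um    | tissue front position                      |

## Experiment record CSV (`write_experiment_record`)

One row per imaging tick. `F_nN = 1000 * k * deflection_um` and
`sigma_Pa = 1000 * F_nN / A_um2` hold exactly per row.

| column        | units | meaning                                  |
|---------------|-------|-------------------------------------------|
| time_s        | s     | master-clock time                          |
| dC_pF         | pF    | filtered capacitance difference C1 - C2    |
| voltage_V     | V     | applied piezo voltage                      |
| X_C_est_um    | um    | chip position from the calibration table   |
| X_T_meas_um   | um    | tracked tip position                       |
| deflection_um | um    | X_T_meas - X_C_est                         |
| F_nN          | nN    | cantilever force                           |
| sigma_Pa      | Pa    | stress over the configured contact area    |

Sidecar `<record>.csv.json`: events (insertion, stall detection,
saturations), full control-config snapshot, seed, spring constant, contact
area.

## Movie files (`write_movie`)

- `<stem>.tif`: multi-page 16-bit grayscale TIFF, one page per frame.
- `<stem>_truth.csv`: columns `frame`, `time_s`, `x_um`, `y_um`
  (ground-truth tip position per frame).
- `<stem>_meta.json`: `n_frames`, `timestamps_s`, `pixel_size_um`,
  `channel`, `fov_px`.

## Tracked trace (data frame; write with `write.csv`)

Columns `time_s`, `x_um`, `y_um`, `confidence` (0-1), `lost`, `bridged`;
attributes `method` and `quality_fail`.

## Cell tracks (`generate_cell_tracks`)

Long format: `cell_id`, `t_s`, `x_um` (antero-posterior), `y_um`
(medial -> lateral positive), nominally 5-min spacing.

## Scenario YAML

See `inst/scenarios/*.yaml`; sections `probe`, `piezo`, `tissue`, `optics`,
`calibration`, `control`, `analysis` plus `name`, `contact_area_um2`,
`duration_s`, `seeds`. `read_scenario`/`write_scenario` are canonical:
load-then-save is byte-identical. Unknown or missing keys are rejected.

## Run manifest JSON (`write_run_manifest`)

`config_hash` (MD5 of the canonical YAML), `seeds`, `package_version`,
`files` (MD5 per output file).
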