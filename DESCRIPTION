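Package: tifmtwin
Title: Digital Twin and Measurement Toolkit for Tissue Force Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a cantilever-based tissue force microscope (piezo
    actuator, capacitive position sensing, elastic cantilever probe) coupled
    to a one-dimensional active-tissue model, and provides the measurement
    software around it: capacitance-to-position calibration, closed-loop
    position hold and constant-force loading, synthetic time-lapse rendering
    of the probe tip in tissue, sub-pixel tip localization and tracking,
    deflection-to-stress conversion with an explicit measurement uncertainty
    budget, and analysis of stall and loading experiments (initial and
    stalling stress, dissipation timescales, elongation speeds, group
    comparisons of cell speeds).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
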