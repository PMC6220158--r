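Package: depspring
Title: Multi-Frequency Dielectrophoretic Characterization of Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the multi-frequency
    dielectrophoresis (DEP) spring, a label-free single-cell electrical
    phenotyping assay. Implements single-shell Clausius-Mossotti factor
    spectra, Monte Carlo sampling of cell dielectric parameters, greedy
    selection of optimal discriminating measurement frequencies under a
    position-uncertainty-derived tolerance, the force-balance spring model
    mapping Re[CM] to a balance position (with inverse, bead-based field
    calibration and cell-size correction), trajectory segmentation and
    balance-position validation, particle detection and tracking from image
    stacks, and 0-1-loss linear discrimination of cell populations from
    multi-frequency Re[CM] features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tiff,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
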