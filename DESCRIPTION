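Package: mlsfm
Title: Multi-Scale Light-Sheet Microscopy Simulation and Acquisition Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator and planning toolkit for multi-scale
    light-sheet fluorescence microscopy (mLSFM) of cleared whole brains.
    Provides closed-form optical models (brightness laws, magnification
    chain, pixel size, diffraction resolution, Gaussian light-sheet
    geometry), seeded synthetic phantoms (branching neuron trees with
    ground truth, sub-resolution bead fields, dye pools, electrode-track
    spike-width data), tiled-light-sheet acquisition simulation with a
    camera noise model, mosaic and sectioning planners with cost
    accounting, a tile-triage signal-detection procedure with false
    positive/negative evaluation, rigid tile stitching and fusion,
    bead-based point-spread-function characterization, and logistic
    boundary localization along electrode tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    EBImage,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
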