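Package: brainsweep
Title: Volumetric Calcium Imaging Pipeline with ETL Remote-Focus Scanning
Version: 0.1.0
Authors@R:
    person("Imaging", "Pipelines", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing whole-brain volumetric calcium imaging
    acquired with an electrically tunable lens (ETL) remote-focusing
    two-photon microscope, as used for larval zebrafish. Covers ETL
    look-up-table calibration and sawtooth drive scheduling, the tilted-plane
    acquisition geometry of a continuously ramping focus, point-spread-function
    metrology on bead stacks, de-interleaving and rigid motion correction of
    interleaved plane streams, nuclear ROI detection and trace extraction,
    regression-based identification of stimulus-responsive neurons with a
    calcium-reporter kernel, and Ward hierarchical clustering of response
    motifs. A synthetic-data module generates brains, activity, rendered
    frame streams, bead stacks and calibration curves with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rhdf5
Config/testthat/edition: 3
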