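Package: pitchpri
Title: Markerless Two-Camera Pitching Kinematics and Ball-Finger
    Positional Relationship Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for markerless two-camera studies of baseball
    pitching. Fits 11-parameter direct linear transformation (DLT) camera
    models from calibration grids, triangulates DeepLabCut-style 2D landmark
    tracks of the ball and finger joints into 3D world trajectories, applies
    zero-phase Butterworth filtering with Winter-style residual analysis,
    detects ball release from the nail-ball separation distance, and extracts
    release parameters (speed, elevation and azimuth release angles) and the
    ball-finger positional relationship index (PRI). Downstream statistics
    include vertical-acceleration phase landmarks and a time-resolved
    across-pitcher Pearson correlation scan linking PRI statistics to
    release-angle variability. A synthetic pitcher-population generator with
    virtual cameras and planted across-pitcher effects supports validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
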