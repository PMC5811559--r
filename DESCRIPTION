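Package: panomap
Title: Panoramic Cardiac Optical Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction and analysis pipeline for panoramic optical mapping
    of cardiac electrophysiology. Calibrates pinhole cameras from a gridded
    cuboid target with Levenberg-Marquardt reprojection minimization,
    reconstructs the epicardial surface from rotation silhouettes by octree
    visual-hull carving with isosurface extraction and Taubin smoothing,
    conditions per-camera fluorescence movies (normalization, spatial binning,
    FIR temporal filtering, drift removal), texture-maps the movies onto the
    triangulated mesh by angle-classified camera assignment with weighted
    gradient blending, and computes activation, action potential duration,
    dominant frequency, phase and phase-singularity maps with Mercator and
    Hammer 2D surface unwrapping. Includes seed-deterministic synthetic
    fixture generators (rendered calibration targets, rotation silhouettes of
    analytic solids, parametric action-potential movies) with exact ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Matrix,
    minpack.lm,
    signal,
    tiff,
    yaml,
    mgcv,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
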