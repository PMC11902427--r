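Package: lgabs
Title: Parametric Simulation of an Active Lumbar Exoskeleton for Ergonomic Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model the assistive torque of a generic active lumbar
    exoskeleton and estimate its biomechanical effect on a motion-captured
    task. Passive (angle-dependent) assistance is represented by
    shape-preserving splines through keypoint tables; active
    (velocity-dependent) assistance by a piecewise-linear law with
    per-percentage thresholds. The package resolves device torque into chest,
    leg-pad and pelvis forces through a sagittal-plane free-body model,
    calibrates keypoint tables from synchronized flexion-angle and load-cell
    recordings, generates fully synthetic capture sets for testing, and
    recomputes a motion-capture-based ergonomic risk score that accounts for
    the device's assistance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
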