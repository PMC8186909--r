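Package: mechanotraj
Title: Trajectory Analysis of Mechanosensitive Channel Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of tethered
    mechanosensitive ion channels gated by intracellular compression
    ("push-to-open"). Provides pore-radius profiling along the permeation axis
    (largest-inscribed-sphere, HOLE-like), essential-dynamics PCA with a
    sharp-change trajectory filter, tilt/rotation angle analysis of the TRP
    domain, restraint reaction-force aggregation with spring-constant,
    planar-torque and force-transfer-speed estimation for the ankyrin-repeat
    spring, ion permeation counting with current and conductance conversion,
    and geometric hydrogen-bond occupancy analysis. A synthetic-systems module
    generates bead-spring supercoils, cylindrical pores with drifting ions,
    rigid-body rotation trajectories and hydrogen-bond toy geometries with
    known ground truth, so every analysis stage is testable without
    molecular-dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
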