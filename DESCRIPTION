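Package: frictiongait
Title: Planar Effective-Friction Simulation of Limbless Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates terrestrial limbless (snake-like) locomotion as a
    planar curve driven by prescribed lateral-curvature and lifting
    (weight-redistribution) traveling waves, propelled by anisotropic
    Coulomb friction against the substrate. Provides the nondimensional
    equations of motion for the centre of mass and mean orientation,
    steady-state gait metrics (pose angle, steering rate, effective
    speed) with behaviour classification, phase-space sweeps over
    lifting amplitude and phase offset with separatrix extraction, and
    heterogeneous friction landscapes (high-friction patches, strips,
    graded lenses, raster fields) for studying passive trajectory
    control, including deflection ensembles and incidence scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    pracma,
    signal,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
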