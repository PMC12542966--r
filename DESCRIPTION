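Package: sprawlsim
Title: Musculoskeletal Inverse Simulation of Sprawling Hindlimb Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inverse musculoskeletal simulation pipeline for sprawling-to-erect
    hindlimb locomotion in crocodylians. From stance-phase kinematics and ground
    reaction forces it computes joint moments (inverse dynamics), resolves muscle
    redundancy by static optimization with reserve and residual actuators,
    propagates joint reaction loads to the femoral midshaft, and evaluates
    beam-theory bone stresses (bending, axial, torsion) and safety factors.
    Includes allometric scaling of models and trials across body sizes up to a
    giant extinct alligatoroid, Hill-type musculotendon mechanics with path-based
    moment arms, cross-sectional geometry from polygon outlines, posture and size
    regressions, and a seeded synthetic-data generator for size-structured gait
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
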