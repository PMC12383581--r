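Package: cusafem
Title: Vibro-Thermal Finite-Element Simulation of Ultrasonic Surgical
    Aspiration in the Cervical Spinal Cord
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the mechanical and thermal action of a Cavitron
    Ultrasonic Surgical Aspirator (CUSA) tip on an intramedullary spinal
    cord tumour embedded in a layered cervical-spine model. Builds a
    parametric labelled solid of vertebrae, intervertebral discs, epidural
    fat, dura mater, cerebrospinal fluid, spinal cord and tumour; meshes it
    with graded tetrahedra; solves the harmonic elastodynamic response to
    the vibrating tip, converts the radiated vibratory power into a surface
    heat flux via the equivalent-radiated-power method, solves transient
    and steady-state bioheat conduction with convective boundaries, and
    evaluates per-tissue maximum temperatures against thermal-damage
    thresholds for spinal cord tissue.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
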