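Package: rheofrac
Title: Fractional Viscoelastic Analysis of Soft-Tissue Oscillatory Rheometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of oscillatory shear rheometry of soft biological
    tissue with three-parameter viscoelastic models. Implements closed-form
    complex moduli and relaxation moduli for the semi-fractional
    Kelvin-Voigt (springpot plus dashpot), fractional Kelvin-Voigt
    (springpot plus spring) and standard linear solid models, a
    Grunwald-Letnikov time-domain oracle for the fractional constitutive
    law, detection of the linear viscoelastic region from strain sweeps,
    inertial-artifact truncation of frequency sweeps, contact-force to
    axial-strain conversion, joint least-squares fitting of storage and
    loss moduli with model comparison, the linear axial-strain dependence
    of the springpot consistence, prediction of step-strain stress
    relaxation from frequency-domain fits, frequency extrapolation of the
    storage modulus, and a seeded synthetic-data generator emulating
    rheometer sweeps for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
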