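Package: alveomech
Title: Multiscale Mechanics of Lung Parenchyma: Alveolar Wall Moduli from
    Uniaxial Stress-Strain Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and inverse estimation for an analytical
    multiscale model of lung parenchymal tissue under uniaxial stretch. The
    tissue is represented as an ensemble of linearly elastic alveolar walls
    that align with, and elongate along, the direction of macroscopic strain
    by incremental energy minimization; macroscopic stress follows from the
    effective wall tensile modulus (Y_ae) and wall-wall bond-bending modulus
    (Y_be). Provides curve simulation, sensitivity analysis, nonlinear
    least-squares estimation of (Y_ae, Y_be) from measured stress-strain
    curves, conversion to per-wall and per-fiber moduli via volume fractions,
    a hexagonal spring-network numerical model (tension-only walls with
    bond-bending) used to validate the analytical model, and generators for
    synthetic quasi-static stress-strain data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
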