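Package: depstretch
Title: Dielectrophoretic Single-Cell Stretching: Maxwell-Stress Simulation
    and Lumped Elongation Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulator for dielectrophoresis (DEP) based stretching
    of single cells between coplanar microelectrodes. Solves the 2-D
    electrostatics of an electrode pair with an embedded dielectric cell,
    evaluates the Maxwell stress tensor traction on the cell boundary, and
    computes the linear-elastic elongation of the cell disk. On top of the
    simulator it provides the explicit lumped elongation law
    L* = S * V^2 * gamma(R, d, w): construction and interpolation of the
    dimensionless geometry factor gamma, estimation of the
    permittivity-contrast exponent, least-squares fitting of the lumped
    cell parameter S from measured elongations, a seeded genetic-algorithm
    optimizer for electrode width and gap, and reduction of measured
    cell-tip trajectories (plateau detection, on/off cycle reversibility)
    including a fully seeded synthetic-trajectory generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
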