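Package: giantmag
Title: Magnetic Vector Tomography, Micromagnetics and Magnetoreception
    Modelling for Giant Magnetofossils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the three-dimensional magnetic structure and
    magnetoreceptive potential of micron-scale biogenic magnetite particles
    (giant magnetofossils).  Builds stacked-frustrum spearhead geometries and
    analytic single-vortex magnetization phantoms with curved cores, Bloch
    points and medial domain walls; simulates dual-axis phase-XMCD projection
    tilt series; reconstructs vector fields by a masked gradient-based
    iterative tomography algorithm; relaxes voxel micromagnetic models of
    magnetite (exchange, cubic anisotropy, FFT demagnetizing field with the
    Newell cell-averaged tensor, Zeeman) including hysteresis, backfield and
    susceptibility protocols; extracts vortex cores, Bloch points and medial
    walls from any vector field; and evaluates the Boltzmann torque-transducer
    model of magnetointensity reception.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
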