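Package: acoustopattern
Title: Acoustic Impulse-Control Simulation for Microparticle Patterning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale two-dimensional simulator for patterning
    microparticles with a circular ultrasonic phased array. Synthesizes
    complex pressure fields by Huygens matrix propagation, converts them
    to acoustic radiation forces on small particles via the Gor'kov
    potential, and integrates particle dynamics with drag and virtual
    mass under rapidly switched drive states. Implements impulse-regime
    control (low, intermediate, high), twin-trap line building,
    standing-wave conveyor belts, focus sweeps and Bessel-order cycling
    for particle clearing and agglomeration, shape-morphing recipes, and
    pattern-contrast metrics on seeded synthetic particle ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
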