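Package: capstim
Title: Capacitive-Coupling Electrical Stimulation Models for Cell-Laden
    Conductive Hydrogels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Equivalent-circuit and axisymmetric electro-quasistatic
    finite-element models of a capacitively coupled electrical
    stimulation chamber used in cartilage tissue engineering.  Computes
    layer and chamber impedances, the electric field delivered to the
    culture medium, the induced transmembrane potential of single cells
    seeded on or embedded in electrically conductive hydrogel scaffolds
    (thin-layer membrane interface), multi-shell equivalent cell
    permittivities and Clausius-Mossotti factors for dielectrophoretic
    force estimates, and propagates parameter uncertainty with Monte
    Carlo and point-collocation polynomial-chaos methods including
    first-order Sobol sensitivity indices and 90 percent prediction
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
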