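Package: scolisim
Title: Patient-Specific Multibody Simulation of Scoliosis Instrumentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasistatic flexible multibody models of the adolescent
    idiopathic scoliosis spine and posterior pedicle-screw instrumentation.
    Generates synthetic three-dimensional scoliotic spine geometry matching
    clinical radiographic indices (Cobb angles, kyphosis, lordosis, apical
    vertebral rotation), assembles rigid vertebrae connected by tension-only
    ligament cables and six-dimensional intervertebral springs, calibrates
    stiffness to functional-spinal-unit and side-bending flexibility data,
    and simulates simultaneous two-rod segmental-translation correction with
    alternative pedicle-screw density patterns, reporting corrected indices
    and bone-screw forces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
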