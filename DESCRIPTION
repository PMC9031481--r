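Package: palsygest
Title: Facial Gesture Recognition from Landmarks in Facial Palsy
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Frame-based recognition of six posed facial gestures (rest,
    eyebrow elevation, eye closure, wide-open smile, closed-mouth smile,
    pucker) from 51 facial landmark coordinates, aimed at faces with
    unilateral facial palsy.  Provides tilt correction by similarity
    transform, 30 handcrafted geometric measures, a 29-element left/right
    asymmetry feature vector, a seeded single-hidden-layer backpropagation
    multilayer perceptron, rotation augmentation, grouped stratified
    five-fold cross-validation with per-class and per-palsy-grade reports,
    a parametric synthetic landmark generator, and ARFF/CSV/JSON
    interoperability with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
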