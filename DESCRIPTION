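Package: aflocate
Title: Locating Re-Entrant Drivers of Atrial Fibrillation from Simulated
    Electrograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A cellular-automaton model of atrial tissue in which atrial
    fibrillation is maintained by re-entrant circuits, together with simulated
    unipolar electrograms, electrogram feature extraction, and a random-forest
    driven recursive search that localizes re-entrant drivers from multiprobe
    electrogram recordings alone. Includes corpus generation for training the
    forests, the constrained search algorithm with its prediction-error
    handling, an extension to tissues with several drivers via expected
    wavefront collisions, and an evaluation harness reporting localization
    success rates and recording counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
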