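Package: orscreen
Title: QSAR Classification and Virtual Screening of Odorant Receptor Agonists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ligand-based reverse chemical ecology toolkit for deorphanizing
    insect odorant receptors. Implements binary QSAR agonist classification
    from molecular descriptors with sphere-exclusion train/test splitting,
    leave-one-out hyperparameter selection driven by the Matthews correlation
    coefficient, a k-nearest-neighbour distance applicability domain with a
    reliability score, consensus virtual screening of volatile libraries, and
    the statistics used to validate predictions by single-sensillum recording
    and Y-tube choice assays. Ships a synthetic-data generator with a planted
    structure-activity rule so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    rpart,
    e1071,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
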