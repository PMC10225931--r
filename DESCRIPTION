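Package: migsfis
Title: Neuro-Fuzzy Treatment Selection for Minimally Invasive Glaucoma
    Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates an adaptive neuro-fuzzy inference system
    (ANFIS) that maps six baseline clinical measurements of a glaucoma
    patient (age, visual acuity, intraocular pressure, visual field mean
    deviation, number of pressure-lowering drops, glaucoma type) to one of
    four minimally-invasive-glaucoma-surgery treatment categories. Fuzzy
    rules are extracted by subtractive clustering governed by a single
    radius-of-influence parameter; a first-order Takagi-Sugeno system with
    Gaussian memberships is then fitted by hybrid learning (exact least
    squares for rule consequents, gradient descent for premise parameters)
    with validation checkpointing. Includes per-class multiclass evaluation
    metrics derived one-vs-rest from the confusion matrix, decision-surface
    grids, a pseudoinverse linear-regression comparator, and a synthetic
    cohort generator with configurable marginal statistics and a planted,
    recoverable rule structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
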