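Package: ripegrade
Title: Fruit Ripeness Discrimination from Bioimpedance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete analysis pipeline for grading fruit ripeness from
    electrical impedance spectroscopy (bioimpedance) sweeps. Simulates
    Cole-dispersion spectra with size coupling and colour-thresholded class
    labels, derives magnitude, phase and loss-tangent curves plus scalar
    indices (Py, minimum phase), screens frequency points by colour-versus-
    size rank correlation, tests size-effect inclusion with nested
    likelihood-ratio comparisons, trains six classifier families under
    uniform class priors with F-beta scoring, performs backward sequential
    feature selection with selection-frequency importance, out-of-bag
    bootstrap validation, a two-stage multi-layer-perceptron architecture
    search, and renders train/test report tables with percent differences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    rpart,
    glmnet,
    withr
Suggests:
    testthat (>= 3.0.0),
    class,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
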