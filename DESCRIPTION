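Package: emtscape
Title: Multi-Program Epithelial-Mesenchymal Transition Scoring from Expression Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores epithelial (E) and mesenchymal (M) gene-set activity per
    sample or cell from bulk and single-cell expression matrices. A nonnegative
    principal component analysis (nnPCA) engine with data deflation exposes
    multiple divergent mesenchymal transcriptional programs (M1, M2, ...) with
    ranked variance explained, alongside rank- and sum-based single-sample
    scorers (ssGSEA, AUCell, SCSE, JASMINE). Samples are clustered in E-M score
    space with a Gaussian mixture model to detect extreme epithelial, extreme
    mesenchymal and hybrid states, and large GMT gene-set collections can be
    screened for processes whose activity correlates with EMT progression.
    Includes synthetic-data generators with planted EMT structure and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
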