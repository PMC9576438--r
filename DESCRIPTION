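Package: rwrdr
Title: Supervised Random Walk with Restart for Drug-Disease Association
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts drug-disease associations by network propagation on a
    protein-protein interaction network. Diseases and drugs are represented
    as seed distributions over network genes; a random walk with restart is
    iterated to its stationary profile; disease-drug pairs are scored by the
    Pearson correlation of their profiles. Known associations can augment the
    seeds (a supervised variant), and a k-fold cross-validation protocol with
    Mann-Whitney AUC evaluates the gain. Includes readers and writers for edge
    lists, GMT-like gene-set files and association tables, a synthetic-data
    generator with plantable signal, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    Matrix,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
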