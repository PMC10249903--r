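Package: aodesrs
Title: Generative AODE Classification with Reliability Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains averaged one-dependence estimation (AODE) classifiers with
    per-class Gaussian-mixture marginal and pairwise-joint densities, and
    computes a model-based reliability score (SRS) for every classified
    instance: the log10 of the best class likelihood, a measure of how well an
    instance matches any trained class. Instances with missing attribute
    values are scored on their present attributes without imputation.
    Includes diagnostic workflows built on the reliability score (detection
    of classes absent from training, two-sample tests for training/application
    distribution shift, missingness profiling, and abstention filtering),
    seeded synthetic-data generators for all of these scenarios, tabular
    input/output, JSON model persistence, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mclust,
    jsonlite,
    rlang,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
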