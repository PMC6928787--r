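Package: lysoacc
Title: Five-Class QSAR Models for Lysosomotropic Cellular Accumulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts five ordinal levels of lysosomotropic cellular
    accumulation of macrocyclic compounds from 2D molecular structure.
    Implements an orthogonal projections to latent structures (OPLS)
    engine with cross-validated selection of orthogonal components, a
    residual-standard-deviation applicability domain, a three-model
    information-fusion scheme in which a model for an imaging-derived
    accumulation surrogate feeds its prediction into the accumulation
    model, evaluation statistics (multi-class balanced accuracy,
    Spearman rank correlation, McNemar's test with continuity
    correction), and a seeded synthetic-data generator with the
    statistical structure of the study design. Computation of the 97
    physicochemical descriptors delegates to RDKit through a bundled
    Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
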