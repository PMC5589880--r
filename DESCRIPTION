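Package: blocklink
Title: Sparse Multiblock Canonical Correlation Pipelines Linking
    Transcriptional and Neuroimaging Blocks to a Clinical Phenotype
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for relating a blood gene-expression block and a
    brain region-of-interest activity block to a binary clinical
    phenotype through regularized and sparse generalized canonical
    correlation analysis (RGCCA/SGCCA) over user-specified block
    designs (sequential, complete, reversed-sequential). Includes
    covariate residualization, univariate differential screening with
    Benjamini-Hochberg adjustment, per-block MANCOVA, externally
    cross-validated linear discriminant classification on latent
    components with fold-stability signature selection, delta-delta-Ct
    relative quantification of qPCR data, and a synthetic multiblock
    generator with planted causal structure for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mixOmics,
    withr
Config/testthat/edition: 3
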