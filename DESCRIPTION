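Package: msclassify
Title: Cross-Platform Classification of Mesenchymal Stromal Cells from
    Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Integrates gene-by-sample expression matrices from multiple
    microarray platforms, rescales each sample by its cumulative expression
    proportion (YuGene), derives a compact multi-component gene signature
    by sparse partial least squares discriminant analysis (sPLS-DA) with
    subsampling-based stability selection and nested-set refinement, and
    classifies new samples as mesenchymal stromal cells (MSC), non-MSC or
    unknown using an ensemble of scores with percentile confidence
    intervals. Ships a synthetic-data generator for multi-dataset
    two-class designs with batch offsets, platform-specific missing genes
    and intermediate differentiating samples, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
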