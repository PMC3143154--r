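Package: TFscape
Title: Integrative Analysis of Transcription-Factor Binding Landscapes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for condition-contrasted transcription
    factor ChIP-seq studies: percentile-scoring peak detection with a
    simulated-read false discovery rate, strand-aware TSS-relative locus
    annotation, four-way cross-condition binding-pattern classification
    (Basal, Shift, Stimulated Only, Unstimulated Only), integration with
    replicate differential-expression calls, position-weight-matrix based
    regulatory network inference with hub-motif screening and
    permutation-tested edges, and clustering-based gene-signature survival
    analysis with Kaplan-Meier / log-rank evaluation. Ships a synthetic-data
    module that plants ground-truth peaks, differentially expressed genes,
    motif instances and prognostic gene groups so every stage is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    survival,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: ChIPSeq, PeakDetection, GeneExpression, Survival,
    NetworkInference, Transcription
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'TFscape-package.R'
    'expression-integration.R'
    'io.R'
    'locus-annotation.R'
    'motif.R'
    'network-inference.R'
    'peak-calling.R'
    'pipeline.R'
    'signature-survival.R'
    'synthetic-data.R'
    'utils.R'
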