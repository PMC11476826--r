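Package: panelqc
Title: Gene-Panel Correlation Quality Control for Mesenchymal Stem Cell Identity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identity quality control for cultured cell populations based on
    correlation of gene expression over a curated gene panel. Provides
    Phred-based cumulative-sum read trimming, RPKM/TPM normalization with
    below-minimum imputation before log transformation, panel-restricted
    squared-correlation (R^2) scoring against median reference profiles,
    coefficient-of-variation discrimination statistics and detection-power
    benchmarking against random gene sets, data-derived acceptance thresholds
    for classifying samples as target MSC, other-tissue MSC, or non-MSC-like,
    passage monitoring, correlation-distance hierarchical clustering with
    Newick export, and a synthetic multi-cell-type expression simulator for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
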