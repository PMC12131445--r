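Package: sctypemap
Title: Whole-Body Single-Cell Expression Mapping with Pseudo-Bulk
    Profiles, Specificity Classification, and Bulk Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds whole-body maps of cell-type gene expression from
    annotated single-cell RNA-seq data. Cells are quality-filtered,
    pooled by cluster into pseudo-bulk profiles, normalized to nTPM
    (TMM-adjusted counts per million), and aggregated into consensus
    cell types. Every gene is classified into five specificity
    categories (cell type enriched, group enriched, enhanced, low
    specificity, not detected) and scored with the tau specificity
    index. Single-cell classifications are compared against bulk
    tissue classifications (Spearman and polyserial concordance,
    paired signed-rank tests, detectability partitions), and bulk
    tissue composition is estimated by dampened weighted least
    squares deconvolution against an enriched-gene signature matrix.
    A synthetic-data generator with planted ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    edgeR,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
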