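#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the number of detected genes (count > 0),
#' total counts, and the percentage of counts falling on
#' mitochondrial-flagged and ribosomal-flagged genes. Cells with zero
#' total counts get percentage fields of 0 (they are always removable
#' via `min_genes >= 1`).
#'
#' @param counts sparse or dense gene x cell count matrix with dimnames.
#' @param mito_genes,ribo_genes character vectors of flagged gene ids;
#'   must be subsets of the matrix rownames.
#' @param metadata optional cell metadata; if it carries a
#'   `doublet_score` column (and `barcode`), the score is joined onto
#'   the result so the table can be filtered directly.
#' @return data.frame with one row per cell: barcode, n_genes_detected,
#'   total_counts, pct_mito, pct_ribo (and doublet_score if available).
#' @export
compute_cell_qc <- function(counts, mito_genes = character(),
                            ribo_genes = character(), metadata = NULL) {
  if (is.null(dim(counts)) || nrow(counts) == 0L || ncol(counts) == 0L) {
    stop("empty count matrix", call. = FALSE)
  }
  counts <- as_count_matrix(counts)
  for (nm in list(c("mito_genes", "mito"), c("ribo_genes", "ribo"))) {
    gs <- get(nm[1])
    if (length(gs) && !all(gs %in% rownames(counts))) {
      stop(sprintf("`%s` contains ids absent from the count matrix", nm[1]),
           call. = FALSE)
    }
  }
  total <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  pct_on <- function(genes) {
    if (!length(genes)) return(rep(0, ncol(counts)))
    sub <- Matrix::colSums(counts[genes, , drop = FALSE])
    ifelse(total > 0, 100 * sub / total, 0)
  }
  qc <- data.frame(barcode = colnames(counts),
                   n_genes_detected = as.integer(detected),
                   total_counts = total,
                   pct_mito = pct_on(mito_genes),
                   pct_ribo = pct_on(ribo_genes),
                   row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(metadata) && all(c("barcode", "doublet_score") %in% names(metadata))) {
    qc$doublet_score <- metadata$doublet_score[match(qc$barcode, metadata$barcode)]
  }
  qc
}

#' Quality-control thresholds, with per-tissue overrides
#'
#' The thresholds mirror organ-specific single-cell QC practice: a cell
#' is kept only if it passes all criteria. Defaults are common-practice
#' values (min 200 detected genes, at most 20% mitochondrial counts,
#' doublet score at most 0.25); each tissue may override any subset of
#' them.
#'
#' @param min_genes,max_genes bounds on detected genes.
#' @param max_pct_mito,max_pct_ribo percentage ceilings.
#' @param max_doublet_score ceiling on the (precomputed) doublet score.
#' @param overrides named list: tissue -> list of fields to override.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = Inf,
                          max_pct_mito = 20, max_pct_ribo = Inf,
                          max_doublet_score = 0.25, overrides = list()) {
  if (is.finite(max_genes) && min_genes > max_genes) {
    stop("`min_genes` must not exceed `max_genes`", call. = FALSE)
  }
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_pct_mito = max_pct_mito, max_pct_ribo = max_pct_ribo,
                 max_doublet_score = max_doublet_score,
                 overrides = overrides),
            class = "qc_thresholds")
}

resolve_thresholds <- function(thresholds, tissue) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  th <- thresholds[c("min_genes", "max_genes", "max_pct_mito",
                     "max_pct_ribo", "max_doublet_score")]
  ov <- thresholds$overrides[[tissue]]
  if (!is.null(ov)) {
    bad <- setdiff(names(ov), names(th))
    if (length(bad)) stop("unknown threshold field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    th[names(ov)] <- ov
  }
  th
}

#' Filter cells on QC thresholds
#'
#' A cell is kept iff it passes every criterion; the removal counts
#' attribute each removed cell to all criteria it fails (a cell failing
#' two criteria appears in both counts but is removed once).
#'
#' @param qc QC metrics table from [compute_cell_qc()]; needs a
#'   `doublet_score` column when `max_doublet_score` is finite.
#' @param thresholds a [qc_thresholds()] object.
#' @param tissue tissue identifier used to resolve per-tissue overrides.
#' @return list with `kept` (barcodes), `removed` (barcodes),
#'   `removal_counts` (named integer per criterion), and the resolved
#'   `thresholds`.
#' @export
filter_cells <- function(qc, thresholds = qc_thresholds(), tissue = "default") {
  th <- resolve_thresholds(thresholds, tissue)
  fails <- cbind(
    min_genes = qc$n_genes_detected < th$min_genes,
    max_genes = qc$n_genes_detected > th$max_genes,
    max_pct_mito = qc$pct_mito > th$max_pct_mito,
    max_pct_ribo = qc$pct_ribo > th$max_pct_ribo,
    max_doublet_score = if (is.finite(th$max_doublet_score)) {
      if (is.null(qc$doublet_score)) {
        stop("`qc` lacks a doublet_score column but `max_doublet_score` is finite",
             call. = FALSE)
      }
      qc$doublet_score > th$max_doublet_score
    } else rep(FALSE, nrow(qc))
  )
  keep <- rowSums(fails) == 0L
  list(kept = qc$barcode[keep],
       removed = qc$barcode[!keep],
       removal_counts = colSums(fails),
       thresholds = th)
}
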