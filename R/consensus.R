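#' Aggregate cluster profiles into consensus cell types
#'
#' The consensus nTPM of a gene in a cell type is the unweighted
#' arithmetic mean over all contributing clusters of that type, so no
#' single large cluster dominates the consensus.
#'
#' @param profile `pseudobulk_profile` or gene x cluster matrix.
#' @param map cluster -> cell type: named character vector, or an
#'   annotation data frame with `cluster` and `cell_type` columns.
#' @return list of class `consensus_profile`: `ntpm` (gene x cell-type
#'   matrix) and `clusters` (cell type -> contributing cluster ids).
#' @export
aggregate_to_cell_types <- function(profile, map) {
  if (is.data.frame(map)) map <- stats::setNames(map$cell_type, map$cluster)
  m <- profile_matrix(profile)
  if (!all(colnames(m) %in% names(map))) {
    stop("unmapped cluster(s): ",
         paste(utils::head(setdiff(colnames(m), names(map)), 5), collapse = ", "),
         call. = FALSE)
  }
  types <- sort(unique(unname(map[colnames(m)])))
  agg <- vapply(types, function(t) {
    rowMeans(m[, colnames(m)[map[colnames(m)] == t], drop = FALSE])
  }, numeric(nrow(m)))
  rownames(agg) <- rownames(m)
  clusters <- lapply(stats::setNames(types, types), function(t) {
    colnames(m)[map[colnames(m)] == t]
  })
  structure(list(ntpm = agg, clusters = clusters), class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("Consensus profile: %d genes x %d cell types (from %d clusters)\n",
              nrow(x$ntpm), ncol(x$ntpm), length(unlist(x$clusters))))
  invisible(x)
}

consensus_matrix <- function(x) {
  if (inherits(x, "consensus_profile")) x$ntpm else as.matrix(x)
}

#' Cell-type composition of each tissue
#'
#' @param metadata cell table with `tissue` and a cell-type (or group)
#'   column.
#' @param by name of the column holding the cell-type assignment.
#' @return tissue x cell-type matrix of fractions; each row sums to 1.
#'   Tissues with zero cells are omitted with a warning.
#' @export
cell_type_fractions <- function(metadata, by = "cell_type") {
  if (!all(c("tissue", by) %in% names(metadata))) {
    stop(sprintf("`metadata` needs columns tissue and %s", by), call. = FALSE)
  }
  tab <- table(metadata$tissue, metadata[[by]])
  totals <- rowSums(tab)
  if (any(totals == 0)) {
    warning("omitting tissue(s) with zero cells: ",
            paste(rownames(tab)[totals == 0], collapse = ", "))
    tab <- tab[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  sweep(unclass(tab), 1, totals, "/")
}

#' Spearman correlation between expression profiles
#'
#' Pairwise Spearman's rho between the columns of a gene x unit matrix
#' (clusters, cell types or tissues), with average ranks on ties.
#' Constant columns have undefined rank correlation; their entries are
#' reported as `NA`.
#'
#' @param x gene x unit matrix with at least 2 units and 3 genes.
#' @return symmetric unit x unit correlation matrix, unit diagonal.
#' @export
spearman_similarity <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) < 2L || nrow(m) < 3L) {
    stop("need at least 2 units and 3 genes", call. = FALSE)
  }
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Agglomerative Ward-D2 dendrogram on 1 - Spearman's rho
#'
#' Hierarchical clustering of units with distance `1 - rho` under the
#' Ward-D2 criterion, the convention behind consensus cell-type
#' dendrograms. Units are ordered by identifier before clustering so
#' ties merge deterministically.
#'
#' @param corr correlation matrix (e.g. [spearman_similarity()]).
#' @return an `hclust` object.
#' @export
ward_dendrogram <- function(corr) {
  corr <- as.matrix(corr)
  if (anyNA(corr)) {
    idx <- which(is.na(corr) & upper.tri(corr), arr.ind = TRUE)
    pairs <- apply(idx, 1, function(i) {
      paste(rownames(corr)[i[1]], colnames(corr)[i[2]], sep = " ~ ")
    })
    stop("missing correlations for pair(s): ", paste(pairs, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(colnames(corr))
  d <- stats::as.dist(1 - corr[ord, ord])
  stats::hclust(d, method = "ward.D2")
}

#' Export a dendrogram as a Newick string
#'
#' @param hc an `hclust`, e.g. from [ward_dendrogram()].
#' @param file optional path; when given the tree is written there.
#' @return the Newick string, invisibly when written to file.
#' @export
as_newick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}

#' Row-wise z-scores of marker expression
#'
#' Transforms each gene row to mean 0 and standard deviation 1 across
#' cell types, so genes of different magnitudes share one color scale.
#' Constant rows become all zeros and are flagged in the `"constant"`
#' attribute.
#'
#' @param profile consensus profile or gene x cell-type matrix.
#' @param genes genes to include; an absent gene is an error.
#' @return gene x cell-type matrix of z-scores.
#' @export
marker_zscore <- function(profile, genes) {
  m <- consensus_matrix(profile)
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) {
    stop("gene(s) absent from profile: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sub <- m[genes, , drop = FALSE]
  mu <- rowMeans(sub)
  sdev <- apply(sub, 1, stats::sd)
  constant <- sdev == 0
  z <- (sub - mu) / ifelse(constant, 1, sdev)
  z[constant, ] <- 0
  attr(z, "constant") <- rownames(sub)[constant]
  z
}

#' Percent-of-max display transform for per-cell read counts
#'
#' Maps each cell's read count of one gene within one tissue to
#' `log2(read_count + 1) / log2(max(read_count) + 1) * 100` and bins
#' the values as `<1%`, `<25%`, `<50%`, `<75%`, `>=75%`. When all
#' counts are zero, every cell gets 0% in the `<1%` bin.
#'
#' @param read_counts nonnegative per-cell counts; at least one cell.
#' @return data.frame with `percent` and ordered factor `bin`.
#' @export
percent_of_max <- function(read_counts) {
  if (!length(read_counts) || any(read_counts < 0)) {
    stop("`read_counts` must be nonnegative and non-empty", call. = FALSE)
  }
  mx <- max(read_counts)
  pct <- if (mx == 0) rep(0, length(read_counts)) else {
    log2(read_counts + 1) / log2(mx + 1) * 100
  }
  labels <- c("<1%", "<25%", "<50%", "<75%", ">=75%")
  bin <- cut(pct, breaks = c(-Inf, 1, 25, 50, 75, Inf), labels = labels,
             right = FALSE)
  data.frame(percent = pct, bin = factor(bin, levels = labels, ordered = TRUE))
}
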