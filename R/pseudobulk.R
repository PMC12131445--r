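#' Pool single-cell counts by cluster
#'
#' Sums UMI counts over all cells of each cluster, producing one
#' pseudo-bulk column per cluster. Pooling conserves the total count
#' and records the number of member cells per cluster.
#'
#' @param counts gene x cell count matrix (sparse or dense, dimnames
#'   required).
#' @param cluster_labels cluster assignment per cell: either a vector
#'   named by barcode or an unnamed vector aligned with the columns.
#' @return list of class `pooled_counts`: `counts` (gene x cluster
#'   dense matrix of summed counts) and `n_cells` (named integer).
#' @export
pool_clusters <- function(counts, cluster_labels) {
  counts <- as_count_matrix(counts)
  if (!is.null(names(cluster_labels))) {
    cluster_labels <- cluster_labels[colnames(counts)]
  }
  if (length(cluster_labels) != ncol(counts) || anyNA(cluster_labels)) {
    stop("every cell must carry a cluster label", call. = FALSE)
  }
  f <- factor(cluster_labels)
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                              dims = c(length(f), nlevels(f)),
                              dimnames = list(NULL, levels(f)))
  pooled <- as.matrix(counts %*% ind)
  structure(list(counts = pooled,
                 n_cells = stats::setNames(as.integer(table(f)), levels(f))),
            class = "pooled_counts")
}

#' @export
print.pooled_counts <- function(x, ...) {
  cat(sprintf("Pooled counts: %d genes x %d clusters (%d cells, %s total counts)\n",
              nrow(x$counts), ncol(x$counts), sum(x$n_cells),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

pooled_matrix <- function(x) {
  if (inherits(x, "pooled_counts")) x$counts else as.matrix(x)
}

#' Counts per million
#'
#' Scales every column to sum to one million. No gene-length term is
#' used: the inputs are UMI counts.
#'
#' @param x pooled counts ([pool_clusters()] result) or a plain matrix.
#' @return gene x cluster CPM matrix.
#' @export
cpm <- function(x) {
  m <- pooled_matrix(x)
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop("cluster(s) with all-zero counts: ",
         paste(colnames(m)[cs == 0], collapse = ", "), call. = FALSE)
  }
  sweep(m, 2, 1e6 / cs, "*")
}

#' TMM scaling factors between pooled clusters
#'
#' Trimmed-mean-of-M-values factors (Robinson & Oshlack) computed with
#' \pkg{edgeR}: the reference column is the one whose upper-quartile
#' expression is closest to the mean upper quartile; each factor is
#' 2^(weighted trimmed mean of M-values against the reference), with
#' inverse asymptotic binomial-variance weights, genes zero in either
#' column excluded, and the factors rescaled to geometric mean 1.
#'
#' @param x pooled counts or matrix.
#' @param trim_M two-sided trim fraction on M-values (default 0.3).
#' @param trim_A two-sided trim fraction on A-values (default 0.05).
#' @return named positive factor per cluster, geometric mean 1.
#' @export
tmm_factors <- function(x, trim_M = 0.3, trim_A = 0.05) {
  m <- pooled_matrix(x)
  if (ncol(m) < 1L) stop("need at least one cluster", call. = FALSE)
  if (ncol(m) == 1L) return(stats::setNames(1, colnames(m)))
  f <- suppressWarnings(
    edgeR::calcNormFactors(m, method = "TMM",
                           logratioTrim = trim_M, sumTrim = trim_A))
  if (any(!is.finite(f) | f <= 0)) {
    warning("no usable common genes for some cluster(s); factor set to 1")
    f[!is.finite(f) | f <= 0] <- 1
    f <- f / exp(mean(log(f)))
  }
  stats::setNames(f, colnames(m))
}

#' Normalized transcripts per million (nTPM)
#'
#' nTPM(g, c) = CPM(g, c) / factor(c), with TMM factors from
#' [tmm_factors()]. When `groups` is supplied (e.g. the tissue of each
#' cluster), factors are computed within each group and the columns
#' re-assembled — matching per-dataset processing where each tissue is
#' quantified separately. Note that nTPM column sums need not equal 1e6
#' once factors differ from 1.
#'
#' @param x pooled counts or matrix.
#' @param groups optional vector (named by cluster or aligned with
#'   columns) grouping clusters, typically by tissue.
#' @param trim_M,trim_A TMM trim fractions, passed to [tmm_factors()].
#' @return object of class `pseudobulk_profile`: list with `ntpm`
#'   (gene x cluster matrix) and `factors` (named per cluster).
#' @export
ntpm <- function(x, groups = NULL, trim_M = 0.3, trim_A = 0.05) {
  m <- pooled_matrix(x)
  cp <- cpm(m)
  if (is.null(groups)) {
    fac <- tmm_factors(m, trim_M, trim_A)
  } else {
    if (!is.null(names(groups))) groups <- groups[colnames(m)]
    if (length(groups) != ncol(m) || anyNA(groups)) {
      stop("`groups` must cover every cluster", call. = FALSE)
    }
    fac <- stats::setNames(numeric(ncol(m)), colnames(m))
    for (g in unique(groups)) {
      idx <- which(groups == g)
      fac[idx] <- tmm_factors(m[, idx, drop = FALSE], trim_M, trim_A)
    }
  }
  structure(list(ntpm = sweep(cp, 2, fac, "/"), factors = fac),
            class = "pseudobulk_profile")
}

#' @export
print.pseudobulk_profile <- function(x, ...) {
  cat(sprintf("Pseudo-bulk nTPM profile: %d genes x %d clusters\n",
              nrow(x$ntpm), ncol(x$ntpm)))
  cat(sprintf("  TMM factors in [%.3f, %.3f], geometric mean %.6f\n",
              min(x$factors), max(x$factors), exp(mean(log(x$factors)))))
  invisible(x)
}

profile_matrix <- function(x) {
  if (inherits(x, "pseudobulk_profile")) x$ntpm else as.matrix(x)
}

#' Drop clusters with unreliable annotation
#'
#' Restricts the profile to clusters whose annotation reliability grade
#' is in `keep` (by default high and medium, excluding low and
#' very-low-grade clusters from downstream analysis). Normalization
#' factors of the retained clusters are untouched.
#'
#' @param profile a `pseudobulk_profile` (or matrix).
#' @param grades reliability per cluster: named character vector with
#'   values among high/medium/low/very_low, or an annotation data frame
#'   with `cluster` and `reliability` columns.
#' @param keep grades to retain.
#' @return filtered object of the same shape as `profile`.
#' @export
filter_reliability <- function(profile, grades, keep = c("high", "medium")) {
  if (is.data.frame(grades)) {
    grades <- stats::setNames(tolower(grades$reliability), grades$cluster)
  } else {
    grades <- stats::setNames(tolower(grades), names(grades))
  }
  valid <- c("high", "medium", "low", "very_low")
  if (!all(grades %in% valid)) {
    stop("grades must be among: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  m <- profile_matrix(profile)
  if (!all(colnames(m) %in% names(grades))) {
    stop("every cluster must be graded; missing: ",
         paste(utils::head(setdiff(colnames(m), names(grades)), 5), collapse = ", "),
         call. = FALSE)
  }
  keep_cols <- colnames(m)[grades[colnames(m)] %in% keep]
  if (!length(keep_cols)) warning("no cluster passes the reliability filter")
  if (inherits(profile, "pseudobulk_profile")) {
    structure(list(ntpm = m[, keep_cols, drop = FALSE],
                   factors = profile$factors[keep_cols]),
              class = "pseudobulk_profile")
  } else {
    m[, keep_cols, drop = FALSE]
  }
}
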