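#' Cross-tabulate two specificity classifications
#'
#' Counts, over the shared gene universe, how many genes carry category
#' i in classification `a` and category j in `b` — the numeric content
#' of alluvial comparisons between single-cell and bulk (or old and
#' new) classifications.
#'
#' @param a,b `specificity_table` objects (or data frames with `gene`
#'   and `category`).
#' @return list with `table` (source x target integer matrix) and `n`
#'   (intersection size). Margins equal each table's category counts on
#'   the intersection.
#' @export
classification_crosstab <- function(a, b) {
  common <- intersect(a$gene, b$gene)
  if (!length(common)) stop("empty gene intersection", call. = FALSE)
  ca <- factor(a$category[match(common, a$gene)], levels = SPECIFICITY_CATEGORIES)
  cb <- factor(b$category[match(common, b$gene)], levels = SPECIFICITY_CATEGORIES)
  list(table = unclass(table(source = ca, target = cb)), n = length(common))
}

#' Spearman concordance of tau scores
#'
#' @param tau_a,tau_b gene-named tau vectors; genes with tau defined in
#'   both are used.
#' @return list with `rho` and `n` (genes used).
#' @export
tau_concordance <- function(tau_a, tau_b) {
  common <- intersect(names(tau_a)[!is.na(tau_a)], names(tau_b)[!is.na(tau_b)])
  if (length(common) < 3L) {
    stop("need at least 3 genes with tau defined in both inputs", call. = FALSE)
  }
  list(rho = stats::cor(tau_a[common], tau_b[common], method = "spearman"),
       n = length(common))
}

#' Polyserial correlation (two-step estimator)
#'
#' Estimates the latent correlation between a continuous variable and
#' an ordinal variable assumed to arise by thresholding a latent
#' standard normal. The two-step (ad hoc) estimator is used:
#' thresholds are `qnorm` of the cumulative level proportions, and
#' `rho = r_xy * s_y / sum(dnorm(thresholds))` where `r_xy` is the
#' Pearson correlation of `x` with the integer-coded ordinal and `s_y`
#' its population standard deviation. The estimate is clamped to
#' \[-1, 1\]. With a binary ordinal this reduces exactly to the
#' textbook biserial correlation.
#'
#' @param x continuous sample.
#' @param y ordinal sample (integer codes or ordered factor); levels
#'   with zero observed count are dropped with a warning.
#' @return list with `rho`, `thresholds`, and `n`.
#' @export
polyserial_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10L) stop("need at least 10 paired observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` is constant", call. = FALSE)
  if (is.factor(y)) {
    if (any(table(y) == 0)) warning("dropping ordinal level(s) with zero count")
    y <- droplevels(y)
    codes <- as.integer(y)
  } else {
    codes <- as.integer(factor(y, levels = sort(unique(y))))
  }
  Klev <- max(codes)
  if (Klev < 2L) stop("need at least 2 ordinal levels present", call. = FALSE)
  props <- tabulate(codes, Klev) / length(codes)
  thresholds <- stats::qnorm(cumsum(props)[-Klev])
  r_xy <- stats::cor(x, codes)
  s_y <- sqrt(mean((codes - mean(codes))^2))   # population sd: binary case
  rho <- r_xy * s_y / sum(stats::dnorm(thresholds))  # matches biserial exactly
  list(rho = max(-1, min(1, rho)), thresholds = thresholds, n = length(x))
}

#' Paired one-sided test that tau_a exceeds tau_b
#'
#' Wilcoxon signed-rank test on the paired tau differences
#' (alternative: `tau_a > tau_b`), the standard paired nonparametric
#' choice for bounded, non-normal scores. Zero differences are dropped
#' per the usual convention.
#'
#' @param tau_a,tau_b gene-named tau vectors.
#' @return list with `statistic`, `p_value`, `n_used` (nonzero
#'   differences) and `method`.
#' @export
paired_tau_test <- function(tau_a, tau_b) {
  common <- intersect(names(tau_a)[!is.na(tau_a)], names(tau_b)[!is.na(tau_b)])
  if (length(common) < 10L) stop("need at least 10 paired genes", call. = FALSE)
  d <- tau_a[common] - tau_b[common]
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                method = "Wilcoxon signed rank (one-sided)"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(tau_a[common], tau_b[common], paired = TRUE,
                       alternative = "greater"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_used = sum(d != 0), method = "Wilcoxon signed rank (one-sided)")
}

#' Partition genes by single-cell vs bulk detectability
#'
#' A gene is "detected" in a dataset when its category there is not
#' `not_detected`. The shared gene universe is split into
#' `both_detected`, `sc_only`, `bulk_only` and `neither`. Bulk-only
#' genes are annotated with their maximum bulk expression and the
#' tissue achieving it; single-cell-only genes with their distribution
#' category across cell types (single / some / many / all).
#'
#' @param sc,bulk `specificity_table` objects.
#' @param bulk_expr gene x tissue bulk expression matrix (for the
#'   bulk-only annotation).
#' @return list of class `detectability_partition` with the four gene
#'   sets, `bulk_only_expr` and `sc_only_distribution` data frames.
#' @export
detectability_partition <- function(sc, bulk, bulk_expr = NULL) {
  common <- intersect(sc$gene, bulk$gene)
  det_sc <- sc$category[match(common, sc$gene)] != "not_detected"
  det_bk <- bulk$category[match(common, bulk$gene)] != "not_detected"
  sets <- list(both_detected = common[det_sc & det_bk],
               sc_only = common[det_sc & !det_bk],
               bulk_only = common[!det_sc & det_bk],
               neither = common[!det_sc & !det_bk])
  bulk_only_expr <- NULL
  if (!is.null(bulk_expr) && length(sets$bulk_only)) {
    sub <- as.matrix(bulk_expr)[sets$bulk_only, , drop = FALSE]
    bulk_only_expr <- data.frame(
      gene = sets$bulk_only,
      max_expr = apply(sub, 1, max),
      max_tissue = colnames(sub)[apply(sub, 1, which.max)],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  sc_only_distribution <- data.frame(
    gene = sets$sc_only,
    distribution = sc$distribution[match(sets$sc_only, sc$gene)],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(c(sets, list(bulk_only_expr = bulk_only_expr,
                         sc_only_distribution = sc_only_distribution,
                         n = length(common))),
            class = "detectability_partition")
}

#' @export
print.detectability_partition <- function(x, ...) {
  cat(sprintf("Detectability over %d shared genes:\n", x$n))
  cat(sprintf("  both detected: %d | single-cell only: %d | bulk only: %d | neither: %d\n",
              length(x$both_detected), length(x$sc_only),
              length(x$bulk_only), length(x$neither)))
  invisible(x)
}
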