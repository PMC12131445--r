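SPECIFICITY_CATEGORIES <- c("enriched", "group_enriched", "enhanced",
                            "low_specificity", "not_detected")
DISTRIBUTION_CATEGORIES <- c("detected_in_all", "detected_in_many",
                             "detected_in_some", "detected_in_single",
                             "not_detected")

#' Parameters of the specificity classifier
#'
#' @param detection_limit nTPM below which a gene counts as undetected
#'   in a cell type (default 1).
#' @param fold_threshold enrichment ratio required for the elevated
#'   categories (default 4, the atlas convention; the categories are a
#'   function of this parameter, not of a hard-coded constant).
#' @param max_group_size largest group considered for the
#'   group-enriched category (default 10).
#' @return object of class `classifier_params`.
#' @export
classifier_params <- function(detection_limit = 1, fold_threshold = 4,
                              max_group_size = 10L) {
  stopifnot_scalar_number(detection_limit, "detection_limit", lower = 1e-12)
  stopifnot_scalar_number(fold_threshold, "fold_threshold", lower = 1 + 1e-12)
  stopifnot_scalar_number(max_group_size, "max_group_size", lower = 2)
  structure(list(detection_limit = detection_limit,
                 fold_threshold = fold_threshold,
                 max_group_size = as.integer(max_group_size)),
            class = "classifier_params")
}

#' Classify one gene's expression profile into a specificity category
#'
#' Assigns one of five mutually exclusive categories from the gene's
#' expression across cell types; the first matching rule wins:
#' \enumerate{
#'   \item `not_detected` — maximum below the detection limit;
#'   \item `enriched` — the unique maximum is at least
#'     `fold_threshold` times the second largest value (and detected);
#'   \item `group_enriched` — the smallest group size g (2 ..
#'     `max_group_size`) whose top-g values (descending, ties broken by
#'     cell-type id) have mean at least `fold_threshold` times the
#'     largest remaining value, every member detected;
#'   \item `enhanced` — some cell type is detected and at least
#'     `fold_threshold` times the mean of all other types; all such
#'     types are reported;
#'   \item `low_specificity` — otherwise.
#' }
#' All comparisons are multiplicative, so zero expression outside the
#' elevated set poses no division problem.
#'
#' @param x nonnegative nTPM vector over at least two cell types;
#'   names, when present, identify the cell types.
#' @param params a [classifier_params()].
#' @return list with `category`, `elevated_types` (character, empty
#'   unless elevated), and `fold` (contrast achieved; `Inf` when the
#'   complement is all zero, `NA` for `not_detected`).
#' @export
classify_gene <- function(x, params = classifier_params()) {
  if (length(x) < 2L) stop("need expression in at least 2 cell types", call. = FALSE)
  if (any(x < 0) || anyNA(x)) stop("expression must be nonnegative", call. = FALSE)
  if (is.null(names(x))) names(x) <- sprintf("t%03d", seq_along(x))
  lim <- params$detection_limit
  f <- params$fold_threshold
  K <- length(x)

  if (max(x) < lim) {
    return(list(category = "not_detected", elevated_types = character(),
                fold = NA_real_))
  }
  ord <- order(-x, names(x))          # descending, stable tie-break by id
  sx <- x[ord]

  if (sx[1] > sx[2] && sx[1] >= lim && sx[1] >= f * sx[2]) {
    return(list(category = "enriched", elevated_types = names(sx)[1],
                fold = if (sx[2] > 0) unname(sx[1] / sx[2]) else Inf))
  }

  gmax <- min(params$max_group_size, K - 1L)
  if (gmax >= 2L) {
    csum <- cumsum(sx)
    for (g in 2:gmax) {
      grp_mean <- csum[g] / g
      rest_max <- sx[g + 1L]
      if (sx[g] >= lim && grp_mean >= f * rest_max) {
        return(list(category = "group_enriched",
                    elevated_types = sort(names(sx)[seq_len(g)]),
                    fold = if (rest_max > 0) unname(grp_mean / rest_max) else Inf))
      }
    }
  }

  s <- sum(x)
  qual <- x >= lim & x * (K - 1) >= f * (s - x)
  if (any(qual)) {
    folds <- ifelse(s - x > 0, x * (K - 1) / (s - x), Inf)
    return(list(category = "enhanced", elevated_types = sort(names(x)[qual]),
                fold = max(folds[qual])))
  }

  list(category = "low_specificity", elevated_types = character(),
       fold = if (sx[2] > 0) unname(sx[1] / sx[2]) else Inf)
}

#' Tau expression-specificity score
#'
#' `tau = sum(1 - x_i / max(x)) / (n - 1)`: 0 for perfectly uniform
#' expression, 1 for expression exclusive to a single cell type. The
#' score is undefined (`NA`) for genes whose maximum falls below the
#' detection limit.
#'
#' @param x nonnegative expression vector over at least two units.
#' @param detection_limit detection limit below which tau is `NA`.
#' @param log_transform apply `log2(x + 1)` before scoring (off by
#'   default; tau is computed on untransformed nTPM).
#' @return tau in \[0, 1\], or `NA`.
#' @export
tau_score <- function(x, detection_limit = 1, log_transform = FALSE) {
  if (length(x) < 2L) stop("need at least 2 units", call. = FALSE)
  if (any(x < 0) || anyNA(x)) stop("expression must be nonnegative", call. = FALSE)
  if (max(x) < detection_limit) return(NA_real_)
  if (log_transform) x <- log2(x + 1)
  sum(1 - x / max(x)) / (length(x) - 1)
}

#' Distribution category: how broadly a gene is detected
#'
#' With d = number of cell types at or above the detection limit and K
#' cell types in total: `not_detected` (d = 0), `detected_in_single`
#' (d = 1), `detected_in_some` (1 < d < K/3), `detected_in_many`
#' (K/3 <= d < K), `detected_in_all` (d = K).
#'
#' @param x nTPM vector over at least 3 cell types.
#' @param params a [classifier_params()] (supplies the detection limit).
#' @return one of the five distribution categories.
#' @export
distribution_category <- function(x, params = classifier_params()) {
  K <- length(x)
  if (K < 3L) stop("need at least 3 cell types", call. = FALSE)
  d <- sum(x >= params$detection_limit)
  if (d == 0) "not_detected"
  else if (d == 1) "detected_in_single"
  else if (d < K / 3) "detected_in_some"
  else if (d < K) "detected_in_many"
  else "detected_in_all"
}

#' Classify every gene of a consensus profile
#'
#' Runs [classify_gene()], [tau_score()] and [distribution_category()]
#' on each gene row and tabulates category counts.
#'
#' @param profile consensus profile or gene x cell-type nTPM matrix.
#' @param params a [classifier_params()].
#' @param log_tau compute tau on `log2(x + 1)` instead of raw nTPM.
#' @return data.frame of class `specificity_table` with one row per
#'   gene: gene, category, elevated_types (semicolon-joined), fold,
#'   tau, distribution. Per-category counts are in
#'   `attr(, "category_counts")`.
#' @export
classify_all <- function(profile, params = classifier_params(), log_tau = FALSE) {
  m <- consensus_matrix(profile)
  n <- nrow(m)
  category <- character(n); elevated <- character(n)
  fold <- numeric(n); tau <- numeric(n); distr <- character(n)
  for (i in seq_len(n)) {
    rec <- classify_gene(m[i, ], params)
    category[i] <- rec$category
    elevated[i] <- paste(rec$elevated_types, collapse = ";")
    fold[i] <- rec$fold
    tau[i] <- tau_score(m[i, ], params$detection_limit, log_tau)
    distr[i] <- distribution_category(m[i, ], params)
  }
  out <- data.frame(gene = rownames(m),
                    category = factor(category, levels = SPECIFICITY_CATEGORIES),
                    elevated_types = elevated, fold = fold, tau = tau,
                    distribution = factor(distr, levels = DISTRIBUTION_CATEGORIES),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "category_counts") <- table(out$category)
  attr(out, "params") <- params
  class(out) <- c("specificity_table", "data.frame")
  out
}

#' @export
print.specificity_table <- function(x, ...) {
  cat(sprintf("Specificity classification of %d genes:\n", nrow(x)))
  counts <- attr(x, "category_counts")
  for (nm in names(counts)) {
    cat(sprintf("  %-16s %6d (%.1f%%)\n", nm, counts[[nm]],
                100 * counts[[nm]] / nrow(x)))
  }
  invisible(x)
}
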