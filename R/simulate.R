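#' Configuration for the synthetic single-cell dataset generator
#'
#' Bundles all parameters of the planted-truth simulator. The defaults
#' describe a compact multi-tissue droplet-style dataset: 2,000 genes,
#' 12 cell types with 2 clusters each (one per synthetic tissue) and
#' 300 cells per cluster, gamma-Poisson (negative binomial) counts with
#' log-normal library sizes, a small complement of mitochondrial and
#' ribosomal genes, planted doublets and planted high-mitochondrial QC
#' outliers, and matched bulk mixtures with multiplicative log-normal
#' noise.
#'
#' @param n_genes number of genes.
#' @param n_cell_types number of distinct cell types.
#' @param clusters_per_type clusters per cell type; cluster `c` of every
#'   type is placed in synthetic tissue `c`, so cell types are shared
#'   across tissues as in real multi-tissue atlases.
#' @param cells_per_cluster cells drawn per cluster (before doublets).
#' @param planted_counts named integer vector giving how many genes to
#'   plant per specificity category; recognised names are `enriched`,
#'   `group_enriched`, `enhanced` and `not_detected`. All remaining
#'   genes are left at the flat baseline and carry the
#'   `low_specificity` ground-truth label. The defaults mirror the
#'   category proportions observed in whole-body single-cell atlases
#'   (about 10% enriched, 14% group enriched, 54% enhanced, 6% not
#'   detected, remainder low specificity).
#' @param fold_factor expression contrast planted for specific genes.
#' @param group_size_range integer interval (within \[2, 10\]) from which
#'   the size of each planted group-enriched set is drawn.
#' @param libsize_logmean,libsize_logsd log-normal parameters of per-cell
#'   library size (total UMI).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param mito_gene_frac,ribo_gene_frac fraction of genes flagged as
#'   mitochondrial / ribosomal.
#' @param doublet_rate fraction of extra cells simulated as doublets.
#' @param qc_outlier_rate fraction of cells given an inflated
#'   mitochondrial load.
#' @param bulk_noise_sd sd of multiplicative log-normal noise applied to
#'   simulated bulk mixtures.
#' @param seed integer seed; all `simulate_*` functions are
#'   deterministic given the configuration.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_cell_types = 12L,
                       clusters_per_type = 2L,
                       cells_per_cluster = 300L,
                       planted_counts = c(enriched = 210L, group_enriched = 270L,
                                          enhanced = 1080L, not_detected = 130L),
                       fold_factor = 8,
                       group_size_range = c(2L, 4L),
                       libsize_logmean = log(5000),
                       libsize_logsd = 0.35,
                       nb_dispersion = 0.4,
                       mito_gene_frac = 0.02,
                       ribo_gene_frac = 0.05,
                       doublet_rate = 0.05,
                       qc_outlier_rate = 0.05,
                       bulk_noise_sd = 0.1,
                       seed = 1L) {
  for (nm in c("n_genes", "n_cell_types", "clusters_per_type", "cells_per_cluster")) {
    stopifnot_scalar_number(get(nm), nm, lower = 1)
  }
  stopifnot_scalar_number(fold_factor, "fold_factor", lower = 1e-8)
  stopifnot_scalar_number(nb_dispersion, "nb_dispersion", lower = 0)
  for (nm in c("mito_gene_frac", "ribo_gene_frac", "doublet_rate", "qc_outlier_rate")) {
    stopifnot_scalar_number(get(nm), nm, lower = 0, upper = 1)
  }
  stopifnot_scalar_number(bulk_noise_sd, "bulk_noise_sd", lower = 0)
  if (length(group_size_range) != 2L || group_size_range[1] > group_size_range[2] ||
      group_size_range[1] < 2L || group_size_range[2] > 10L) {
    stop("`group_size_range` must be an increasing integer interval within [2, 10]",
         call. = FALSE)
  }
  known <- c("enriched", "group_enriched", "enhanced", "low_specificity", "not_detected")
  if (length(planted_counts) && (is.null(names(planted_counts)) ||
      !all(names(planted_counts) %in% known))) {
    stop("`planted_counts` names must be specificity categories: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  planted <- stats::setNames(integer(length(known)), known)
  planted[names(planted_counts)] <- as.integer(planted_counts)
  if (any(planted < 0)) stop("planted counts must be nonnegative", call. = FALSE)
  n_signal <- sum(planted[c("enriched", "group_enriched", "enhanced", "not_detected")])
  if (n_signal + planted["low_specificity"] > n_genes) {
    stop("sum of planted category counts exceeds `n_genes`", call. = FALSE)
  }
  if (group_size_range[2] >= n_cell_types && planted["group_enriched"] > 0) {
    stop("`group_size_range` upper bound must be below `n_cell_types`", call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes), n_cell_types = as.integer(n_cell_types),
    clusters_per_type = as.integer(clusters_per_type),
    cells_per_cluster = as.integer(cells_per_cluster),
    planted_counts = planted, fold_factor = fold_factor,
    group_size_range = as.integer(group_size_range),
    libsize_logmean = libsize_logmean, libsize_logsd = libsize_logsd,
    nb_dispersion = nb_dispersion, mito_gene_frac = mito_gene_frac,
    ribo_gene_frac = ribo_gene_frac, doublet_rate = doublet_rate,
    qc_outlier_rate = qc_outlier_rate, bulk_noise_sd = bulk_noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic dataset configuration\n")
  cat(sprintf("  %d genes x %d cell types, %d cluster(s)/type, %d cells/cluster\n",
              x$n_genes, x$n_cell_types, x$clusters_per_type, x$cells_per_cluster))
  cat("  planted genes:",
      paste(sprintf("%s=%d", names(x$planted_counts), x$planted_counts), collapse = ", "),
      "\n")
  cat(sprintf("  fold_factor=%g, nb_dispersion=%g, doublet_rate=%g, seed=%d\n",
              x$fold_factor, x$nb_dispersion, x$doublet_rate, x$seed))
  invisible(x)
}

sim_gene_ids <- function(config) {
  n_mito <- round(config$mito_gene_frac * config$n_genes)
  n_ribo <- round(config$ribo_gene_frac * config$n_genes)
  ids <- sprintf("G%05d", seq_len(config$n_genes))
  is_mito <- seq_len(config$n_genes) <= n_mito
  is_ribo <- !is_mito & seq_len(config$n_genes) <= n_mito + n_ribo
  ids[is_mito] <- sprintf("MT-G%04d", seq_len(n_mito))
  ids[is_ribo] <- sprintf("RP-G%04d", seq_len(n_ribo))
  data.frame(gene = ids, is_mito = is_mito, is_ribo = is_ribo,
             stringsAsFactors = FALSE)
}

#' Simulate cell-type mean-expression profiles with planted specificity
#'
#' Draws a log-normal baseline mean for every gene, applies a small
#' per-cell-type jitter, and then plants the requested number of genes
#' per specificity category so that the downstream classifier can
#' recover them:
#' \itemize{
#'   \item `enriched`: one target type multiplied by `fold_factor`
#'     (targets cycle over all types so every type receives markers);
#'   \item `group_enriched`: a group of types (size drawn from
#'     `group_size_range`) multiplied by `fold_factor` while the
#'     remaining types are divided by it, giving the strongly bimodal
#'     profile characteristic of real group-enriched genes;
#'   \item `enhanced`: the non-target types get a log-normal spread,
#'     the largest of them is floored, and the target is set to
#'     `0.55 * fold_factor` times the mean of the rest — elevated over
#'     the mean of the other types without dominating the second
#'     largest, i.e. moderately elevated;
#'   \item `not_detected`: the whole row is scaled down so expected
#'     nTPM stays below 1 in every cell type.
#' }
#' Mitochondrial (x5) and ribosomal (x2) genes get a raised baseline so
#' simulated cells carry realistic mito/ribo count fractions.
#'
#' @param config a [sim_config()].
#' @return A list with `means` (gene x cell-type matrix of expected
#'   relative expression), `gene_meta` (gene, is_mito, is_ribo), and
#'   `truth` — a data frame with each gene's planted category, target
#'   cell types (semicolon-joined) and planted fold.
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_cell_types
  types <- sprintf("celltype_%02d", seq_len(K))
  gene_meta <- sim_gene_ids(config)
  n <- config$n_genes

  with_seed(config$seed, {
    base <- stats::rlnorm(n, meanlog = log(20), sdlog = 1)
    base[gene_meta$is_mito] <- base[gene_meta$is_mito] * 5
    base[gene_meta$is_ribo] <- base[gene_meta$is_ribo] * 2
    means <- base * matrix(stats::rlnorm(n * K, 0, 0.1), n, K)
    dimnames(means) <- list(gene_meta$gene, types)

    category <- rep("low_specificity", n)
    target_types <- rep("", n)
    fold <- rep(NA_real_, n)

    eligible <- which(!gene_meta$is_mito & !gene_meta$is_ribo)
    pc <- config$planted_counts
    n_plant <- sum(pc[c("enriched", "group_enriched", "enhanced", "not_detected")])
    planted_idx <- sample(eligible, n_plant)
    split_at <- cumsum(pc[c("enriched", "group_enriched", "enhanced", "not_detected")])
    idx_enr <- planted_idx[seq_len(split_at[1])]
    idx_grp <- planted_idx[seq_len(split_at[2])][-seq_len(split_at[1])]
    idx_enh <- planted_idx[seq_len(split_at[3])][-seq_len(split_at[2])]
    idx_nd  <- planted_idx[seq_len(split_at[4])][-seq_len(split_at[3])]

    # enriched: one type raised; targets cycle so all types are covered
    if (length(idx_enr)) {
      tgt <- rep_len(seq_len(K), length(idx_enr))
      means[cbind(idx_enr, tgt)] <- means[cbind(idx_enr, tgt)] * config$fold_factor
      category[idx_enr] <- "enriched"
      target_types[idx_enr] <- types[tgt]
      fold[idx_enr] <- config$fold_factor
    }

    # group enriched: members raised, non-members suppressed
    if (length(idx_grp)) {
      gsr <- config$group_size_range
      for (j in seq_along(idx_grp)) {
        g <- idx_grp[j]
        size <- if (gsr[1] == gsr[2]) gsr[1] else sample(seq(gsr[1], gsr[2]), 1L)
        start <- ((j - 1L) %% K)
        members <- ((start + seq_len(size) - 1L) %% K) + 1L
        means[g, members] <- means[g, members] * config$fold_factor
        means[g, -members] <- means[g, -members] / config$fold_factor
        category[g] <- "group_enriched"
        target_types[g] <- paste(types[sort(members)], collapse = ";")
        fold[g] <- config$fold_factor
      }
    }

    # enhanced: non-target types follow a graded ramp (1.4x .. 0.6x the
    # gene baseline, mean 1, mild jitter) and the target sits at
    # 1.1 * (fold_factor/2) * mean(rest) — elevated over the mean of
    # the other types but, given the ramp, never fold_factor/2 times
    # the second-largest value nor part of a qualifying group prefix,
    # so a classifier with fold threshold fold_factor/2 calls it
    # enhanced.
    if (length(idx_enh)) {
      tgt <- rep_len(seq_len(K), length(idx_enh))
      ramp <- seq(1.4, 0.6, length.out = K - 1L)
      ramp <- ramp / mean(ramp)
      for (j in seq_along(idx_enh)) {
        g <- idx_enh[j]
        rest <- setdiff(seq_len(K), tgt[j])
        vals <- mean(means[g, rest]) * sample(ramp) *
          stats::rlnorm(K - 1L, 0, 0.05)
        means[g, rest] <- vals
        means[g, tgt[j]] <- 1.1 * (config$fold_factor / 2) * mean(vals)
        category[g] <- "enhanced"
        target_types[g] <- types[tgt[j]]
        fold[g] <- 1.1 * config$fold_factor / 2
      }
    }

    # not detected: push the whole row far below the detection limit
    if (length(idx_nd)) {
      means[idx_nd, ] <- means[idx_nd, ] * 1e-4
      category[idx_nd] <- "not_detected"
    }

    truth <- data.frame(gene = gene_meta$gene, category = category,
                        target_types = target_types, fold = fold,
                        stringsAsFactors = FALSE)
    list(means = means, gene_meta = gene_meta, truth = truth)
  })
}

nb_counts <- function(mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(length(mu), mu))
  shape <- 1 / dispersion
  stats::rpois(length(mu), mu * stats::rgamma(length(mu), shape = shape, rate = shape))
}

#' Simulate UMI counts and cell metadata from mean profiles
#'
#' Draws per-cell library sizes log-normally and gamma-Poisson counts
#' around `library size x relative expression` of the cell's type.
#' Planted QC outliers get a tenfold boost of their mitochondrial
#' relative expression (renormalised), planted doublets are extra cells
#' whose expected profile averages two distinct parent types; doublets
#' carry a synthetic doublet score of 0.9 against a 0.05 baseline.
#'
#' @param profiles result of [simulate_profiles()].
#' @param config the same [sim_config()].
#' @return A list with `counts` (sparse gene x cell matrix), `metadata`
#'   (barcode, tissue, cluster, doublet_score), `cell_truth` (true
#'   cluster/type, is_doublet, is_qc_outlier), and `annotation` — a
#'   cluster annotation table (cluster, tissue, cell_type,
#'   cell_type_group, reliability, n_cells) with all clusters graded
#'   "high".
#' @export
simulate_counts <- function(profiles, config) {
  stopifnot(inherits(config, "sim_config"))
  means <- profiles$means
  if (is.null(means) || ncol(means) != config$n_cell_types) {
    stop("`profiles$means` must have `n_cell_types` columns", call. = FALSE)
  }
  if (nrow(means) == 0L) stop("empty profiles", call. = FALSE)
  K <- config$n_cell_types
  types <- colnames(means)
  tissues <- sprintf("tissue_%02d", seq_len(config$clusters_per_type))
  rel <- sweep(means, 2, colSums(means), "/")
  mito_idx <- which(profiles$gene_meta$is_mito)

  with_seed(config$seed + 1L, {
    clusters <- expand.grid(type = seq_len(K), rep = seq_len(config$clusters_per_type))
    cluster_id <- sprintf("%s_c%d", types[clusters$type], clusters$rep)
    n_base <- nrow(clusters) * config$cells_per_cluster
    cell_cluster <- rep(seq_len(nrow(clusters)), each = config$cells_per_cluster)

    n_doub <- round(config$doublet_rate * n_base)
    n_cells <- n_base + n_doub
    barcodes <- sprintf("cell%06d", seq_len(n_cells))
    libsize <- stats::rlnorm(n_cells, config$libsize_logmean, config$libsize_logsd)

    is_outlier <- logical(n_cells)
    is_outlier[sample(n_base, round(config$qc_outlier_rate * n_base))] <- TRUE
    is_doublet <- c(rep(FALSE, n_base), rep(TRUE, n_doub))

    # doublets: two distinct parent types; hosted in a random cluster of
    # the first parent so they hide inside real clusters
    doub_a <- doub_b <- integer(0)
    if (n_doub > 0) {
      doub_a <- sample(K, n_doub, replace = TRUE)
      doub_b <- vapply(doub_a, function(a) sample(setdiff(seq_len(K), a), 1L), 1L)
      host <- vapply(doub_a, function(a) {
        sample(which(clusters$type == a), 1L)
      }, 1L)
      cell_cluster <- c(cell_cluster, host)
    }

    cols <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      t_i <- clusters$type[cell_cluster[i]]
      p <- if (is_doublet[i]) {
        (rel[, doub_a[i - n_base]] + rel[, doub_b[i - n_base]]) / 2
      } else rel[, t_i]
      if (is_outlier[i] && length(mito_idx)) {
        p[mito_idx] <- p[mito_idx] * 10
        p <- p / sum(p)
      }
      cols[[i]] <- nb_counts(libsize[i] * p, config$nb_dispersion)
    }
    counts <- Matrix::Matrix(
      matrix(unlist(cols, use.names = FALSE), nrow = nrow(means), ncol = n_cells,
             dimnames = list(rownames(means), barcodes)),
      sparse = TRUE)

    metadata <- data.frame(
      barcode = barcodes,
      tissue = tissues[clusters$rep[cell_cluster]],
      cluster = cluster_id[cell_cluster],
      doublet_score = ifelse(is_doublet, 0.9, 0.05),
      stringsAsFactors = FALSE)
    cell_truth <- data.frame(
      barcode = barcodes,
      cluster = cluster_id[cell_cluster],
      cell_type = types[clusters$type[cell_cluster]],
      is_doublet = is_doublet,
      is_qc_outlier = is_outlier,
      stringsAsFactors = FALSE)
    annotation <- data.frame(
      cluster = cluster_id,
      tissue = tissues[clusters$rep],
      cell_type = types[clusters$type],
      cell_type_group = sprintf("group_%d", ((clusters$type - 1L) %/% 3L) + 1L),
      reliability = "high",
      n_cells = as.integer(table(factor(cell_cluster, levels = seq_len(nrow(clusters))))),
      stringsAsFactors = FALSE)
    list(counts = counts, metadata = metadata, cell_truth = cell_truth,
         annotation = annotation)
  })
}

#' Simulate bulk tissue mixtures from cell-type profiles
#'
#' Forms each bulk column as `profiles %*% proportions` with
#' multiplicative log-normal noise of sd `bulk_noise_sd` (noiseless at
#' 0) — the forward model that deconvolution inverts.
#'
#' @param profiles gene x cell-type matrix of mean expression (or the
#'   list returned by [simulate_profiles()]).
#' @param proportions cell-type x tissue matrix (or a single vector) of
#'   mixing proportions; every column must lie on the simplex.
#' @param config a [sim_config()] (supplies `bulk_noise_sd` and seed).
#' @return gene x tissue matrix.
#' @export
simulate_bulk <- function(profiles, proportions, config) {
  stopifnot(inherits(config, "sim_config"))
  means <- if (is.list(profiles)) profiles$means else profiles
  if (is.null(dim(proportions))) {
    proportions <- matrix(proportions, ncol = 1,
                          dimnames = list(names(proportions), "bulk_1"))
  }
  if (nrow(proportions) != ncol(means)) {
    stop("`proportions` rows must match profile cell types", call. = FALSE)
  }
  if (any(proportions < 0) || any(abs(colSums(proportions) - 1) > 1e-9)) {
    stop("every proportion vector must be nonnegative and sum to 1 (tol 1e-9)",
         call. = FALSE)
  }
  if (is.null(colnames(proportions))) {
    colnames(proportions) <- sprintf("bulk_%d", seq_len(ncol(proportions)))
  }
  bulk <- means %*% proportions
  if (config$bulk_noise_sd > 0) {
    noise <- with_seed(config$seed + 2L,
      matrix(stats::rlnorm(length(bulk), 0, config$bulk_noise_sd),
             nrow(bulk), ncol(bulk)))
    bulk <- bulk * noise
  }
  bulk
}

#' Simulate a latent bivariate-normal sample with an ordinal margin
#'
#' Draws `(X, Y*)` standard bivariate normal with correlation `rho` and
#' discretises `Y*` at `thresholds` into ordered categories `1..K+1`.
#' Used as the oracle input for the polyserial estimator.
#'
#' @param rho latent correlation, strictly inside (-1, 1).
#' @param thresholds strictly increasing cut points on the latent scale.
#' @param n sample size.
#' @param seed integer seed.
#' @return list with numeric `x` and integer ordinal `y`.
#' @export
simulate_bivariate_ordinal <- function(rho, thresholds, n, seed = 1L) {
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) >= 1) {
    stop("`rho` must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (length(thresholds) < 1L || is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  }
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    ystar <- rho * z1 + sqrt(1 - rho^2) * z2
    list(x = z1, y = findInterval(ystar, thresholds) + 1L)
  })
}

#' Write a simulated dataset as a 10x-style triplet directory
#'
#' Writes the sparse count matrix (MatrixMarket), gene and barcode TSVs,
#' the cell metadata TSV, the cluster annotation TSV and the ground
#' truth as JSON.
#'
#' @param sim result of [simulate_counts()].
#' @param profiles result of [simulate_profiles()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, profiles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_10x_triplet(sim$counts, dir)
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(genes = profiles$truth, cells = sim$cell_truth)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
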