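#' Run the full expression-mapping pipeline
#'
#' Executes the stages end to end: per-cell QC and filtering, cluster
#' pooling, nTPM normalization (TMM within tissue), reliability
#' filtering, consensus cell-type aggregation, specificity
#' classification — and, when a bulk table is supplied, the
#' bulk-vs-single-cell comparison and DWLS deconvolution. All stage
#' artifacts are written to `out_dir` as TSV/JSON/Newick files plus a
#' run manifest; outputs are byte-identical across reruns with the
#' same inputs and seed.
#'
#' @param config a named list (or path to a YAML/JSON file) with
#'   entries:
#'   \describe{
#'     \item{counts}{gene x cell count matrix, or path to a 10x triplet
#'       directory.}
#'     \item{metadata}{cell metadata (barcode, tissue, cluster,
#'       doublet_score), or a TSV path.}
#'     \item{annotation}{cluster annotation table or TSV path (see
#'       [read_annotation()]).}
#'     \item{bulk}{optional gene x tissue bulk expression matrix or TSV
#'       path; when absent, comparison and deconvolution are skipped.}
#'     \item{out_dir}{output directory.}
#'     \item{mito_genes, ribo_genes}{optional flagged gene sets
#'       (defaults: ids starting `MT-` / `RP`).}
#'     \item{thresholds}{optional [qc_thresholds()].}
#'     \item{params}{optional [classifier_params()].}
#'     \item{keep_grades}{reliability grades to keep (default high,
#'       medium).}
#'     \item{seed}{integer seed (used for DWLS fold assignment).}
#'   }
#' @param quiet suppress stage messages.
#' @return list of class `sctypemap_run` with the main in-memory
#'   results and `artifacts` (paths written).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  say <- function(stage, ...) if (!quiet) message(sprintf("[%s] ", stage), ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out_dir <- config$out_dir %||% stop("`config$out_dir` is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  emit <- function(name) {
    path <- file.path(out_dir, name)
    artifacts <<- c(artifacts, path)
    path
  }

  counts <- stage("input", {
    if (is.character(config$counts)) read_10x_triplet(config$counts)
    else as_count_matrix(config$counts)
  })
  metadata <- stage("input", {
    if (is.character(config$metadata)) {
      utils::read.delim(config$metadata, stringsAsFactors = FALSE)
    } else config$metadata
  })
  annotation <- stage("input", {
    if (is.character(config$annotation)) read_annotation(config$annotation)
    else config$annotation
  })
  bulk <- stage("input", {
    if (is.null(config$bulk)) NULL
    else if (is.character(config$bulk)) read_matrix_tsv(config$bulk)
    else as.matrix(config$bulk)
  })
  mito_genes <- config$mito_genes %||% grep("^MT-", rownames(counts), value = TRUE)
  ribo_genes <- config$ribo_genes %||% grep("^RP", rownames(counts), value = TRUE)
  thresholds <- config$thresholds %||% qc_thresholds()
  params <- config$params %||% classifier_params()
  keep_grades <- config$keep_grades %||% c("high", "medium")
  seed <- config$seed %||% 1L

  # --- QC ---------------------------------------------------------------
  qc <- stage("qc", compute_cell_qc(counts, mito_genes, ribo_genes, metadata))
  kept <- character(0)
  report <- list()
  for (ti in unique(metadata$tissue)) {
    cells_ti <- metadata$barcode[metadata$tissue == ti]
    flt <- stage("qc", filter_cells(qc[qc$barcode %in% cells_ti, ], thresholds, ti))
    kept <- c(kept, flt$kept)
    report[[ti]] <- list(n_input = length(cells_ti), n_kept = length(flt$kept),
                         removal_counts = as.list(flt$removal_counts))
  }
  say("qc", sprintf("%d / %d cells kept", length(kept), nrow(metadata)))
  utils::write.table(qc, emit("qc_metrics.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report, emit("filter_report.json"), auto_unbox = TRUE,
                       digits = NA)

  # --- pooling and normalization ---------------------------------------
  labels <- stats::setNames(metadata$cluster, metadata$barcode)[kept]
  pooled <- stage("pool", pool_clusters(counts[, kept, drop = FALSE], labels))
  cluster_tissue <- stats::setNames(annotation$tissue, annotation$cluster)
  profile <- stage("ntpm", ntpm(pooled, groups = cluster_tissue))
  say("ntpm", sprintf("%d clusters normalized", ncol(profile$ntpm)))
  write_matrix_tsv(pooled$counts, emit("pooled_counts.tsv"))
  write_matrix_tsv(profile$ntpm, emit("ntpm.tsv"))
  utils::write.table(
    data.frame(cluster = names(profile$factors), factor = profile$factors),
    emit("tmm_factors.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  # --- reliability filter and consensus --------------------------------
  reliable <- stage("reliability", filter_reliability(profile, annotation, keep_grades))
  say("reliability", sprintf("%d / %d clusters retained", ncol(reliable$ntpm),
                             ncol(profile$ntpm)))
  consensus <- stage("consensus", aggregate_to_cell_types(reliable, annotation))
  meta_kept <- metadata[metadata$barcode %in% kept, ]
  meta_kept$cell_type <- annotation$cell_type[match(meta_kept$cluster,
                                                    annotation$cluster)]
  fractions <- stage("consensus", cell_type_fractions(meta_kept))
  corr <- stage("consensus", spearman_similarity(consensus$ntpm))
  tree <- stage("consensus", ward_dendrogram(corr))
  write_matrix_tsv(consensus$ntpm, emit("consensus_ntpm.tsv"))
  write_matrix_tsv(fractions, emit("cell_type_fractions.tsv"), id_name = "tissue")
  write_matrix_tsv(corr, emit("spearman_correlation.tsv"), id_name = "cell_type")
  as_newick(tree, emit("celltype_tree.nwk"))

  # --- classification ---------------------------------------------------
  records <- stage("classify", classify_all(consensus, params))
  say("classify", paste(sprintf("%s=%d", names(attr(records, "category_counts")),
                                attr(records, "category_counts")), collapse = ", "))
  utils::write.table(records, emit("classification.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(attr(records, "category_counts")),
                       emit("category_summary.json"), auto_unbox = TRUE,
                       digits = NA)

  comparison <- deconv <- bulk_records <- NULL
  if (is.null(bulk)) {
    say("compare", "no bulk table supplied; skipping comparison and deconvolution")
  } else {
    # --- comparison vs bulk --------------------------------------------
    common <- intersect(rownames(consensus$ntpm), rownames(bulk))
    bulk_records <- stage("compare", classify_all(bulk[common, , drop = FALSE], params))
    crosstab <- stage("compare", classification_crosstab(records, bulk_records))
    tau_sc <- stats::setNames(records$tau, records$gene)
    tau_bk <- stats::setNames(bulk_records$tau, bulk_records$gene)
    conc <- stage("compare", tau_concordance(tau_sc, tau_bk))
    ptest <- stage("compare", paired_tau_test(tau_sc, tau_bk))
    part <- stage("compare", detectability_partition(records, bulk_records, bulk))
    not_nd <- records$category[match(names(tau_sc), records$gene)] != "not_detected"
    ord <- factor(records$category[match(names(tau_sc)[not_nd], records$gene)],
                  levels = c("low_specificity", "enhanced", "group_enriched",
                             "enriched"), ordered = TRUE)
    poly <- stage("compare", polyserial_correlation(tau_sc[not_nd][!is.na(ord)],
                                                    ord[!is.na(ord)]))
    comparison <- list(crosstab = crosstab, tau_spearman = conc,
                       polyserial = poly, paired_test = ptest, partition = part)
    write_matrix_tsv(crosstab$table, emit("crosstab.tsv"), id_name = "single_cell")
    jsonlite::write_json(
      list(tau_spearman = conc$rho, n_tau = conc$n, polyserial = poly$rho,
           paired_p = ptest$p_value),
      emit("concordance.json"), auto_unbox = TRUE, digits = NA)

    # --- deconvolution --------------------------------------------------
    sig <- stage("deconvolve", build_signature(consensus, records))
    deconv <- stage("deconvolve", deconvolve_all(sig, bulk[rownames(sig$S), ,
                                                           drop = FALSE],
                                                 fold_seed = seed))
    write_matrix_tsv(sig$S, emit("signature.tsv"))
    write_matrix_tsv(deconv$proportions, emit("proportions.tsv"),
                     id_name = "tissue")
    jsonlite::write_json(deconv$top, emit("top_celltypes.json"),
                         dataframe = "rows", digits = NA)
    say("deconvolve", sprintf("%d tissue(s) deconvolved", nrow(deconv$proportions)))
  }

  manifest <- list(
    package = "sctypemap",
    version = as.character(utils::packageVersion("sctypemap")),
    seed = seed,
    parameters = list(thresholds = unclass(thresholds)[
                        setdiff(names(thresholds), "overrides")],
                      classifier = unclass(params),
                      keep_grades = keep_grades),
    n_cells_input = nrow(metadata), n_cells_kept = length(kept),
    n_clusters = ncol(profile$ntpm), n_clusters_reliable = ncol(reliable$ntpm),
    n_cell_types = ncol(consensus$ntpm), n_genes = nrow(consensus$ntpm),
    artifacts = basename(artifacts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(qc = qc, profile = profile, consensus = consensus,
                 records = records, bulk_records = bulk_records,
                 comparison = comparison, deconvolution = deconv,
                 artifacts = c(artifacts, file.path(out_dir, "manifest.json"))),
            class = "sctypemap_run")
}

#' @export
print.sctypemap_run <- function(x, ...) {
  cat("sctypemap pipeline run\n")
  cat(sprintf("  %d genes x %d consensus cell types\n",
              nrow(x$consensus$ntpm), ncol(x$consensus$ntpm)))
  print(x$records)
  if (!is.null(x$deconvolution)) {
    cat(sprintf("  deconvolved %d bulk profile(s)\n",
                nrow(x$deconvolution$proportions)))
  }
  invisible(x)
}
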