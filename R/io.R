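find_triplet_file <- function(dir, stems) {
  for (stem in stems) for (ext in c("", ".gz")) {
    p <- file.path(dir, paste0(stem, ext))
    if (file.exists(p)) return(p)
  }
  stop("none of ", paste(stems, collapse = "/"), " found in ", dir, call. = FALSE)
}

read_id_column <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  as.character(df[[1]])
}

#' Read a 10x-style triplet directory
#'
#' Reads a MatrixMarket sparse count matrix together with its gene and
#' barcode lists (`matrix.mtx`, `genes.tsv`/`features.tsv`,
#' `barcodes.tsv`, plain or gzipped) and validates that the stated
#' dimensions match the id files. Duplicate gene ids are disambiguated
#' with [make.unique()] and a warning.
#'
#' @param dir directory holding the three files.
#' @return sparse gene x cell `dgCMatrix` with dimnames.
#' @export
read_10x_triplet <- function(dir) {
  mtx <- find_triplet_file(dir, "matrix.mtx")
  genes <- read_id_column(find_triplet_file(dir, c("genes.tsv", "features.tsv")))
  barcodes <- read_id_column(find_triplet_file(dir, "barcodes.tsv"))
  m <- tryCatch(Matrix::readMM(mtx), error = function(e) {
    stop("malformed MatrixMarket file ", mtx, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
    stop(sprintf("dimension mismatch in %s: matrix is %d x %d but %d genes / %d barcodes listed",
                 dir, nrow(m), ncol(m), length(genes), length(barcodes)),
         call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    warning("duplicate gene ids disambiguated with make.unique()")
    genes <- make.unique(genes)
  }
  dimnames(m) <- list(genes, barcodes)
  as_count_matrix(m)
}

#' Write a count matrix as a 10x-style triplet directory
#'
#' @param counts gene x cell matrix (sparse or dense) with dimnames.
#' @param dir output directory (created if missing).
#' @param gzip gzip the three files.
#' @return `dir`, invisibly.
#' @export
write_10x_triplet <- function(counts, dir, gzip = FALSE) {
  counts <- as_count_matrix(counts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".gz" else ""
  mtx_plain <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(counts, mtx_plain)
  if (gzip) {
    con_in <- readLines(mtx_plain)
    con <- gzfile(paste0(mtx_plain, ".gz"), "w")
    writeLines(con_in, con); close(con)
    unlink(mtx_plain)
  }
  write_ids <- function(ids, stem) {
    path <- file.path(dir, paste0(stem, ext))
    con <- if (gzip) gzfile(path, "w") else file(path, "w")
    writeLines(ids, con); close(con)
  }
  write_ids(rownames(counts), "genes.tsv")
  write_ids(colnames(counts), "barcodes.tsv")
  invisible(dir)
}

#' Read a cluster annotation table
#'
#' Expects a TSV with columns cluster, tissue, cell_type,
#' cell_type_group, reliability, n_cells. Reliability grades are
#' matched case-insensitively against high / medium / low / very_low;
#' duplicate cluster ids are an error.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("cluster", "tissue", "cell_type", "cell_type_group",
                "reliability", "n_cells")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("annotation lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$reliability <- gsub(" ", "_", tolower(df$reliability))
  bad <- setdiff(unique(df$reliability), c("high", "medium", "low", "very_low"))
  if (length(bad)) {
    stop("unknown reliability grade(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$cluster)) {
    stop("duplicate cluster id(s): ",
         paste(unique(df$cluster[duplicated(df$cluster)]), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write / read a numeric matrix as TSV with a leading id column
#'
#' The canonical table dialect of the package: tab-separated, header
#' row, '.' decimal, no quoting; the first column (`gene` by default)
#' holds the row ids.
#'
#' @param x matrix with dimnames.
#' @param path file path.
#' @param id_name name of the leading id column.
#' @return `path` (write) or the matrix (read), invisibly for write.
#' @export
write_matrix_tsv <- function(x, path, id_name = "gene") {
  df <- data.frame(rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
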