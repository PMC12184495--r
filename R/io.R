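# Delimited IO. Numeric text is written with 17 significant digits so a
# write/read round trip reproduces doubles exactly.

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

#' Read a gene x sample counts file
#'
#' Expects a TSV/CSV with a header row of sample ids and gene ids in the
#' first column (delimiter auto-detected by `data.table::fread`).
#'
#' @param path counts file path.
#' @param labels_path optional one-column label file (0/1, header optional),
#'   aligned with the sample columns; all-baseline labels assumed if absent.
#' @return A [counts_table()].
#' @export
read_counts_tsv <- function(path, labels_path = NULL) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  gene_ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  labels <- if (is.null(labels_path)) rep(0L, ncol(m)) else read_labels(labels_path)
  counts_table(m, gene_ids, colnames(m), labels)
}

#' Read a MatrixMarket single-cell counts triplet
#'
#' Reads an MTX file with gene and barcode sidecar files (first column of
#' each sidecar used as identifier). The matrix is densified on load.
#'
#' @param mtx_path MatrixMarket file (genes x cells).
#' @param genes_path,barcodes_path sidecar id files.
#' @param labels_path optional one-column label file aligned with barcodes.
#' @return A [counts_table()].
#' @export
read_counts_mtx <- function(mtx_path, genes_path, barcodes_path,
                            labels_path = NULL) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  genes <- data.table::fread(genes_path, header = FALSE, data.table = FALSE)[[1]]
  cells <- data.table::fread(barcodes_path, header = FALSE, data.table = FALSE)[[1]]
  labels <- if (is.null(labels_path)) rep(0L, length(cells)) else read_labels(labels_path)
  counts_table(m, genes, cells, labels)
}

#' Read a two-column gene-length table
#' @param path TSV with columns gene id, transcript length (header optional).
#' @return Named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  stats::setNames(as.numeric(dt[[2]]), as.character(dt[[1]]))
}

#' Read a one-column binary label file
#' @param path file with one 0/1 label per line (optional header).
#' @return Integer vector.
#' @export
read_labels <- function(path) {
  v <- data.table::fread(path, header = "auto", data.table = FALSE)[[1]]
  as.integer(v)
}

#' Write a counts table (and companion label file)
#' @param counts a [counts_table()].
#' @param path output counts TSV (gene x sample, header = sample ids).
#' @param labels_path optional output path for the one-column label file.
#' @export
write_counts_tsv <- function(counts, path, labels_path = NULL) {
  df <- data.frame(gene = counts$gene_ids,
                   counts$values, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  if (!is.null(labels_path))
    writeLines(c("label", as.character(counts$labels)), labels_path)
  invisible(path)
}

#' Write a numeric matrix as full-precision TSV
#' @param m numeric matrix (row names kept as a leading `id` column).
#' @param path output file.
#' @export
write_matrix_tsv <- function(m, path) {
  chr <- matrix(fmt_num(m), nrow = nrow(m))
  df <- data.frame(id = if (is.null(rownames(m))) seq_len(nrow(m)) else rownames(m),
                   chr, check.names = FALSE)
  colnames(df) <- c("id", if (is.null(colnames(m))) paste0("V", seq_len(ncol(m))) else colnames(m))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path input file.
#' @return Numeric matrix with row and column names restored.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Write an expression set (values TSV + label file)
#' @param expr an [expression_set()].
#' @param prefix output path prefix; writes `<prefix>_expr.tsv` and
#'   `<prefix>_labels.tsv`.
#' @return Invisibly, the two paths written.
#' @export
write_expression_tsv <- function(expr, prefix) {
  p1 <- paste0(prefix, "_expr.tsv")
  p2 <- paste0(prefix, "_labels.tsv")
  write_matrix_tsv(expr$values, p1)
  writeLines(c("label", as.character(expr$labels)), p2)
  invisible(c(p1, p2))
}

#' Read an expression set written by [write_expression_tsv()]
#' @param prefix the prefix used when writing.
#' @return An [expression_set()].
#' @export
read_expression_tsv <- function(prefix) {
  m <- read_matrix_tsv(paste0(prefix, "_expr.tsv"))
  labels <- read_labels(paste0(prefix, "_labels.tsv"))
  expression_set(m, labels, gene_ids = colnames(m), sample_ids = rownames(m))
}

# Compact binary matrix container (run-time artifact only; a simple
# gzip-compressed header + little-endian doubles).
#' Write a matrix in the compact binary container
#' @param m numeric matrix.
#' @param path output file.
#' @export
write_matrix_bin <- function(m, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeBin(as.double(c(nrow(m), ncol(m))), con, size = 8, endian = "little")
  writeBin(as.double(m), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a matrix from the compact binary container
#' @param path input file.
#' @return Numeric matrix.
#' @export
read_matrix_bin <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  dims <- readBin(con, "double", 2, size = 8, endian = "little")
  matrix(readBin(con, "double", prod(dims), size = 8, endian = "little"),
         nrow = dims[1], ncol = dims[2])
}
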