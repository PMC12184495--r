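#' Construct a raw counts table
#'
#' Container for a genes x samples matrix of non-negative integer counts with
#' per-sample binary phenotype labels (0 = baseline, 1 = variant).
#'
#' @param values genes x samples numeric matrix of non-negative counts.
#' @param gene_ids character vector, unique, length `nrow(values)`.
#' @param sample_ids character vector, unique, length `ncol(values)`.
#' @param labels integer/numeric vector in \{0, 1\}, length `ncol(values)`.
#' @return An object of class `counts_table`.
#' @export
counts_table <- function(values, gene_ids, sample_ids, labels) {
  values <- as.matrix(values)
  if (any(values < 0)) stopf("counts must be non-negative")
  if (anyDuplicated(gene_ids) || length(gene_ids) != nrow(values))
    stopf("gene_ids must be unique and match nrow(values)")
  if (anyDuplicated(sample_ids) || length(sample_ids) != ncol(values))
    stopf("sample_ids must be unique and match ncol(values)")
  if (length(labels) != ncol(values) || !is_binary01(labels))
    stopf("labels must be binary (0/1) and length ncol(values)")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids),
                 labels = as.integer(labels)),
            class = "counts_table")
}

#' Construct a normalized expression set
#'
#' Samples x genes matrix on the log-NTPM scale (`log10(NTPM + 1e-10) + 10`,
#' hence non-negative) with binary phenotype labels.
#'
#' @param values samples x genes numeric matrix.
#' @param labels binary vector (0 = baseline, 1 = variant), length `nrow(values)`.
#' @param gene_ids,sample_ids identifier vectors matched to the matrix dims.
#' @return An object of class `expression_set` with fields `values`, `labels`,
#'   `label_onehot` (n x 2, columns baseline/variant), `gene_ids`, `sample_ids`.
#' @export
expression_set <- function(values, labels, gene_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%05d", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(nrow(values)))
  if (length(labels) != nrow(values) || !is_binary01(labels))
    stopf("labels must be binary and length nrow(values)")
  if (length(gene_ids) != ncol(values)) stopf("gene_ids length mismatch")
  if (length(sample_ids) != nrow(values)) stopf("sample_ids length mismatch")
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, labels = as.integer(labels),
                 label_onehot = encode_labels(labels),
                 gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids)),
            class = "expression_set")
}

#' @export
print.counts_table <- function(x, ...) {
  cat(sprintf("<counts_table> %d genes x %d samples (%d baseline / %d variant)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == 0), sum(x$labels == 1)))
  invisible(x)
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d samples x %d genes (%d baseline / %d variant)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == 0), sum(x$labels == 1)))
  invisible(x)
}

#' @export
print.eigengene_basis <- function(x, ...) {
  cat(sprintf("<eigengene_basis> %d genes, rank bound l = %d, top sigma = %.4g\n",
              nrow(x$U), x$l, x$singular_values[1]))
  invisible(x)
}

#' @export
print.finemap_result <- function(x, ...) {
  cat(sprintf("<finemap_result> d = %d, top PIP = %.3f, acceptance rate = %.2f\n",
              length(x$pip), max(x$pip), x$acceptance_rate))
  invisible(x)
}

#' @export
print.perturbation_library <- function(x, ...) {
  cat(sprintf("<perturbation_library> %d eigengenes x %d perturbations (%d KD / %d OE)\n",
              nrow(x$B), ncol(x$B),
              sum(x$perturbation_meta$sign == "KD"),
              sum(x$perturbation_meta$sign == "OE")))
  invisible(x)
}

#' @export
print.cooc_stats <- function(x, ...) {
  cat(sprintf("<cooc_stats> %d perturbations over N = %d accepted rows, max z = %.2f\n",
              nrow(x$f), x$n_rows, suppressWarnings(max(x$z[upper.tri(x$z)]))))
  invisible(x)
}
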