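#' Filter a counts table by sample depth and gene abundance
#'
#' Samples whose total count does not exceed `min_sample_total` are dropped
#' first; genes are then kept when their mean count over the surviving samples
#' strictly exceeds `min_gene_mean`. Both inequalities are strict. The sample
#' filter is applied before the gene filter so per-gene means are not diluted
#' by failed libraries; one pass each, no iteration.
#'
#' @param counts a [counts_table()].
#' @param min_gene_mean gene retained iff mean count > this (default 5).
#' @param min_sample_total sample retained iff total count > this (default 1e5).
#' @return The filtered [counts_table()].
#' @export
filter_counts <- function(counts, min_gene_mean = 5, min_sample_total = 1e5) {
  stopifnot(inherits(counts, "counts_table"))
  if (nrow(counts$values) == 0 || ncol(counts$values) == 0)
    stopf("empty counts table")
  keep_s <- colSums(counts$values) > min_sample_total
  if (!any(keep_s)) stopf("all samples removed by the total-count filter (> %g)",
                          min_sample_total)
  v <- counts$values[, keep_s, drop = FALSE]
  keep_g <- rowMeans(v) > min_gene_mean
  if (!any(keep_g)) stopf("all genes removed by the mean-count filter (> %g)",
                          min_gene_mean)
  counts_table(v[keep_g, , drop = FALSE],
               counts$gene_ids[keep_g],
               counts$sample_ids[keep_s],
               counts$labels[keep_s])
}

#' Normalize counts to transcripts per million (NTPM)
#'
#' Per sample, each gene's count is converted to a transcript rate
#' `count / length`; rates are rescaled so every sample sums to 1e6.
#'
#' @param counts a [counts_table()].
#' @param lengths named numeric vector of transcript lengths in bases; must
#'   cover every gene in `counts` with a positive value.
#' @return samples x genes numeric matrix of NTPM values.
#' @export
normalize_ntpm <- function(counts, lengths) {
  stopifnot(inherits(counts, "counts_table"))
  miss <- setdiff(counts$gene_ids, names(lengths))
  if (length(miss) > 0)
    stopf("missing transcript lengths for: %s",
          paste(utils::head(miss, 10), collapse = ", "))
  len <- as.numeric(lengths[counts$gene_ids])
  if (any(!is.finite(len)) || any(len <= 0))
    stopf("all retained genes need positive finite lengths")
  rate <- counts$values / len                 # genes x samples
  tot <- colSums(rate)
  if (any(tot <= 0)) stopf("zero total transcript rate in sample(s): %s",
                           paste(counts$sample_ids[tot <= 0], collapse = ", "))
  ntpm <- t(rate) * (1e6 / tot)               # samples x genes
  dimnames(ntpm) <- list(counts$sample_ids, counts$gene_ids)
  ntpm
}

#' Log-transform NTPM values
#'
#' Elementwise `log10(x + 1e-10) + 10`, mapping NTPM of 0 to exactly 0 and
#' keeping all outputs non-negative.
#'
#' @param ntpm non-negative numeric matrix (or vector).
#' @return Transformed matrix of the same shape.
#' @export
log_transform <- function(ntpm) {
  if (any(ntpm < 0)) stopf("negative values are not valid NTPM input")
  log10(ntpm + 1e-10) + 10
}

#' One-hot encode binary phenotype labels
#'
#' @param labels vector in \{0, 1\} (0 = baseline, 1 = variant).
#' @return n x 2 matrix with columns `baseline`, `variant`; each row sums to 1.
#' @export
encode_labels <- function(labels) {
  if (!is_binary01(labels)) stopf("labels must be 0/1")
  out <- cbind(baseline = as.numeric(labels == 0),
               variant  = as.numeric(labels == 1))
  out
}

#' Curate a raw counts table into normalized expression
#'
#' Runs the full curation chain: sample/gene filtering, NTPM normalization,
#' log transform, and label one-hot encoding.
#'
#' @inheritParams filter_counts
#' @inheritParams normalize_ntpm
#' @return An [expression_set()] on the log-NTPM scale.
#' @export
curate_counts <- function(counts, lengths, min_gene_mean = 5,
                          min_sample_total = 1e5) {
  f <- filter_counts(counts, min_gene_mean, min_sample_total)
  expr <- log_transform(normalize_ntpm(f, lengths))
  expression_set(expr, f$labels, gene_ids = f$gene_ids, sample_ids = f$sample_ids)
}
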