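#' Compute the eigengene basis of an expression matrix
#'
#' Thin singular value decomposition of `t(Y)` for a samples x genes matrix
#' `Y`: `t(Y) = U diag(sigma) t(V)`, whose columns of `U` (gene space) are the
#' eigengenes, ordered by descending singular value. The matrix is used as
#' given (no centering by default; eigengene 1 then tracks the mean profile).
#' Column signs are fixed deterministically: the largest-magnitude entry of
#' each eigengene is made positive.
#'
#' @param Y samples x genes numeric matrix, or an [expression_set()].
#' @param center center genes before decomposition (default `FALSE`).
#' @return Object of class `eigengene_basis`: `U` (genes x l),
#'   `singular_values`, `V` (samples x l), `l = min(m, n)`, `center`.
#' @export
compute_basis <- function(Y, center = FALSE) {
  if (inherits(Y, "expression_set")) Y <- Y$values
  if (!all(is.finite(Y))) stopf("expression matrix contains non-finite entries")
  if (center) Y <- sweep(Y, 2, colMeans(Y))
  s <- svd(t(Y))
  flip <- vapply(seq_len(ncol(s$u)),
                 function(i) s$u[which.max(abs(s$u[, i])), i] < 0,
                 logical(1))
  s$u[, flip] <- -s$u[, flip]
  s$v[, flip] <- -s$v[, flip]
  structure(list(U = s$u, singular_values = s$d, V = s$v,
                 l = min(dim(Y)), center = center),
            class = "eigengene_basis")
}

#' Project expression data onto the top-d eigengenes
#'
#' `X = Y U[, 1:d]`, the coordinates of each sample in the reduced eigengene
#' basis. Errors (rather than silently truncating) if `d` exceeds the rank
#' bound.
#'
#' @param Y samples x genes matrix or [expression_set()] (same gene order as
#'   the basis).
#' @param basis an `eigengene_basis`.
#' @param d number of eigengenes to keep (default 200).
#' @return Object of class `projected_data`: `X` (samples x d), `d`,
#'   `eigengene_indices`.
#' @export
project_eigengenes <- function(Y, basis, d = 200) {
  if (inherits(Y, "expression_set")) Y <- Y$values
  stopifnot(inherits(basis, "eigengene_basis"))
  if (d > basis$l)
    stopf("d = %d exceeds the available rank l = %d", d, basis$l)
  if (ncol(Y) != nrow(basis$U)) stopf("gene dimension mismatch with basis")
  X <- Y %*% basis$U[, seq_len(d), drop = FALSE]
  structure(list(X = X, d = d, eigengene_indices = seq_len(d)),
            class = "projected_data")
}

#' Fraction of variance beyond the top-d eigengenes
#'
#' `sum(sigma_i^2, i > d) / sum(sigma_i^2)`.
#'
#' @param basis an `eigengene_basis`.
#' @param d number of retained eigengenes.
#' @return Fraction in [0, 1].
#' @export
variance_remaining <- function(basis, d) {
  stopifnot(inherits(basis, "eigengene_basis"))
  if (d > basis$l) stopf("d exceeds the available rank l = %d", basis$l)
  s2 <- basis$singular_values^2
  if (d == 0) return(1)
  sum(s2[-seq_len(d)]) / sum(s2)
}
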