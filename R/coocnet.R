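# Co-occurrence statistics over accepted steering solutions and the
# maximum-entropy bipartite null model with fixed expected row/column sums.

#' Observed co-occurrence frequencies
#'
#' `f = A'A / N` for a binary occurrence matrix with N rows: the fraction of
#' accepted pair-solutions in which each pair of perturbations co-occurs.
#'
#' @param A binary rows x perturbations matrix.
#' @return P x P symmetric matrix.
#' @export
cooccurrence_freq <- function(A) {
  A <- as.matrix(A)
  if (!is_binary01(A)) stopf("A must be binary")
  if (nrow(A) < 1) stopf("A must have at least one row")
  crossprod(A) / nrow(A)
}

#' Fit the maximum-entropy bipartite null model
#'
#' Finds row multipliers `beta_i` and column multipliers `gamma_j` such that
#' the independent-Bernoulli ensemble `p_ij = 1/(1 + exp(-(beta_i + gamma_j)))`
#' reproduces the observed row sums `k_i` and column sums `kappa_j` in
#' expectation. Multipliers are obtained by damped fixed-point iteration of
#' `beta_i <- log k_i - log sum_j r(beta_i, gamma_j)` (and symmetrically for
#' `gamma_j`) with `r(x, y) = 1/(exp(-y) + exp(x))`; sums run over all
#' opposite-side indices (bipartite convention — rows and columns index
#' different entities, so no diagonal exclusion applies). Saturated or empty
#' rows/columns are removed before fitting and re-inserted with `p` fixed to
#' 1 or 0.
#'
#' @param A binary matrix.
#' @param tol convergence tolerance on the max-norm change of `p`
#'   (default 1e-10).
#' @param max_iter iteration cap (default 1e5).
#' @param damping step mixing in (0, 1]; 0.5 by default for stability.
#' @return Object of class `null_model`: `beta_row`, `gamma_col` (NA for
#'   removed rows/cols), `p` (full-size edge-probability matrix),
#'   `converged`, `iterations`.
#' @export
fit_null <- function(A, tol = 1e-10, max_iter = 1e5, damping = 0.5) {
  A <- as.matrix(A)
  if (!is_binary01(A)) stopf("A must be binary")
  N <- nrow(A); M <- ncol(A)
  k <- rowSums(A); kap <- colSums(A)
  keep_r <- k > 0 & k < M
  keep_c <- kap > 0 & kap < N
  p_full <- matrix(0, N, M)
  p_full[k == M, ] <- 1
  p_full[, kap == N] <- 1
  # also honor zero rows/cols
  p_full[k == 0, ] <- 0
  p_full[, kap == 0] <- 0
  beta_full <- rep(NA_real_, N); gam_full <- rep(NA_real_, M)
  if (any(keep_r) && any(keep_c)) {
    Ar <- A[keep_r, keep_c, drop = FALSE]
    kr <- rowSums(Ar); kc <- colSums(Ar)
    if (any(kr == 0) || any(kr == ncol(Ar)) || any(kc == 0) ||
        any(kc == nrow(Ar))) {
      # removing saturated lines can saturate others; recurse on the submatrix
      sub <- fit_null(Ar, tol, max_iter, damping)
      p_full[keep_r, keep_c] <- sub$p
      beta_full[keep_r] <- sub$beta_row
      gam_full[keep_c] <- sub$gamma_col
      return(structure(list(beta_row = beta_full, gamma_col = gam_full,
                            p = p_full, converged = sub$converged,
                            iterations = sub$iterations),
                       class = "null_model"))
    }
    n <- nrow(Ar); m <- ncol(Ar)
    beta <- logit(pmin(pmax(kr / m, 1e-6), 1 - 1e-6))
    gam <- rep(0, m)
    p_of <- function(beta, gam) sigmoid(outer(beta, gam, `+`))
    p_old <- p_of(beta, gam)
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      # r(beta_i, gam_j) = 1/(exp(-gam_j) + exp(beta_i)); row sums of r give
      # the update for beta, column sums (with roles swapped) for gamma
      rmat <- 1 / outer(exp(beta), exp(-gam), `+`)
      beta_new <- log(kr) - log(rowSums(rmat))
      # r(gamma_j, beta_i) = 1/(exp(-beta_i) + exp(gamma_j)), beta at step l
      rmat2 <- 1 / outer(exp(gam), exp(-beta), `+`)
      gam_new <- log(kc) - log(rowSums(rmat2))
      beta <- damping * beta_new + (1 - damping) * beta
      gam <- damping * gam_new + (1 - damping) * gam
      p_new <- p_of(beta, gam)
      if (max(abs(p_new - p_old)) < tol) { converged <- TRUE; p_old <- p_new; break }
      p_old <- p_new
    }
    if (!converged) {
      res_r <- max(abs(rowSums(p_old) - kr))
      res_c <- max(abs(colSums(p_old) - kc))
      stopf("null model did not converge in %d iterations (residuals: rows %.3g, cols %.3g)",
            as.integer(max_iter), res_r, res_c)
    }
    p_full[keep_r, keep_c] <- p_old
    beta_full[keep_r] <- beta
    gam_full[keep_c] <- gam
  }
  structure(list(beta_row = beta_full, gamma_col = gam_full, p = p_full,
                 converged = TRUE, iterations = if (exists("it")) it else 0L),
            class = "null_model")
}

#' Expected co-occurrence frequencies under the null
#'
#' `<f> = p'p / N` with `p` the fitted edge-probability matrix.
#'
#' @param null a `null_model`.
#' @return P x P symmetric matrix.
#' @export
expected_freq <- function(null) {
  stopifnot(inherits(null, "null_model"))
  crossprod(null$p) / nrow(null$p)
}

#' Standard error of null co-occurrence frequencies
#'
#' Error propagation under independent Bernoulli cells:
#' `sigma^2 = sum_alpha p_am p_an (1 - p_am p_an) / N^2` (the variance of a
#' mean of independent Bernoulli products).
#'
#' @param null a `null_model`.
#' @return P x P matrix of standard errors (0 where z is undefined).
#' @export
sigma_freq <- function(null) {
  stopifnot(inherits(null, "null_model"))
  N <- nrow(null$p)
  q <- crossprod(null$p)            # sum_a p_am p_an
  q2 <- crossprod(null$p^2)         # sum_a (p_am p_an)^2
  v <- (q - q2) / N^2
  sqrt(pmax(v, 0))
}

#' Full co-occurrence statistics for an occurrence matrix
#'
#' Computes observed frequencies, fits the maximum-entropy null, and derives
#' expected frequencies, standard errors and z-scores
#' `z = (f - <f>)/sigma` (0, flagged, where `sigma = 0`).
#'
#' @param A binary occurrence matrix (rows = accepted pair-solutions).
#' @param null optionally a pre-fitted `null_model` (e.g. to score new
#'   matrices sampled from a fixed null).
#' @param ... forwarded to [fit_null()].
#' @return Object of class `cooc_stats`: `f`, `f_null`, `sigma`, `z`,
#'   `undefined` (logical matrix of sigma = 0 cells), `n_rows`, `null`.
#' @export
cooccurrence_stats <- function(A, null = NULL, ...) {
  f <- cooccurrence_freq(A)
  if (is.null(null)) null <- fit_null(A, ...)
  f_null <- expected_freq(null)
  sig <- sigma_freq(null)
  undefined <- sig == 0
  z <- matrix(0, nrow(f), ncol(f), dimnames = dimnames(f))
  z[!undefined] <- (f[!undefined] - f_null[!undefined]) / sig[!undefined]
  structure(list(f = f, f_null = f_null, sigma = sig, z = z,
                 undefined = undefined, n_rows = nrow(A), null = null),
            class = "cooc_stats")
}

#' Z-score matrix of co-occurrence statistics
#'
#' @param stats a `cooc_stats`.
#' @return P x P symmetric matrix (0 in flagged undefined cells).
#' @export
z_scores <- function(stats) {
  stopifnot(inherits(stats, "cooc_stats"))
  stats$z
}

#' Sample an occurrence matrix from a fitted null model
#'
#' Independent Bernoulli draws at the fitted `p_ij` (used for null
#' calibration of the z-scores).
#'
#' @param null a `null_model`.
#' @param seed integer seed.
#' @return Binary matrix with the dimensions of the fitted data.
#' @export
sample_null <- function(null, seed = 1L) {
  stopifnot(inherits(null, "null_model"))
  with_seed(seed, {
    matrix(rbinom(length(null$p), 1, as.numeric(null$p)),
           nrow(null$p), ncol(null$p))
  })
}

#' Quantile-quantile points of the z-score distribution
#'
#' Sorted observed z-values against standard-normal quantiles at plotting
#' positions `(i - 0.5)/n`, for choosing the network threshold by inspection.
#'
#' @param z numeric matrix or vector of z-scores (off-diagonal upper triangle
#'   used when a matrix is given).
#' @return data.frame with columns `theoretical`, `observed`.
#' @export
qq_points <- function(z) {
  v <- if (is.matrix(z)) z[upper.tri(z)] else as.numeric(z)
  v <- v[is.finite(v)]
  if (length(v) < 2) stopf("need at least 2 finite z values")
  v <- sort(v)
  n <- length(v)
  data.frame(theoretical = qnorm((seq_len(n) - 0.5) / n), observed = v)
}

#' Build the thresholded co-occurrence network
#'
#' Edges connect perturbation pairs with `z` strictly above `threshold`;
#' nodes are the perturbations (gene symbol + sign) involved in at least one
#' significant pair. Edge attribute `correlation` carries the response-profile
#' correlation; node attribute `degree` the connection count.
#'
#' @param z P x P z-score matrix.
#' @param threshold z threshold (strict; default 20, re-thresholdable by
#'   inspecting [qq_points()]).
#' @param meta per-perturbation data.frame (`column`, `gene`, `sign`).
#' @param response_correlations P x P correlation matrix of response profiles.
#' @return An `igraph` graph (possibly empty).
#' @export
build_cooc_graph <- function(z, threshold = 20, meta = NULL,
                             response_correlations = NULL) {
  if (!is.finite(threshold)) stopf("threshold must be finite")
  P <- ncol(z)
  if (is.null(meta))
    meta <- data.frame(column = sprintf("pert%03d", seq_len(P)),
                       gene = sprintf("pert%03d", seq_len(P)),
                       sign = rep("KD", P), stringsAsFactors = FALSE)
  idx <- which(upper.tri(z) & z > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) return(igraph::make_empty_graph(directed = FALSE))
  nodes <- sort(unique(c(idx[, 1], idx[, 2])))
  labs <- paste0(meta$gene, ifelse(meta$sign == "OE", "+", "-"))
  edges <- data.frame(from = labs[idx[, 1]], to = labs[idx[, 2]],
                      z = z[idx],
                      correlation = if (is.null(response_correlations)) NA_real_
                                    else response_correlations[idx])
  vert <- data.frame(name = labs[nodes], gene = meta$gene[nodes],
                     sign = meta$sign[nodes])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vert)
  igraph::V(g)$degree <- igraph::degree(g)
  g
}
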