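# Bounded L1-penalized steering: find u in [0,1]^P minimizing
# ||x_to - x_from - B u|| + lambda * sum(u), the sparse combination of
# perturbation responses that moves one cell state onto another in
# causal-eigengene coordinates.

#' Build a perturbation library in causal-eigengene coordinates
#'
#' Projects each gene-space response profile onto the selected causal
#' eigengenes (`B = U[, selected]' responses`) and computes the P x P Pearson
#' correlation matrix of the full-gene response profiles (used to annotate
#' co-occurrence edges).
#'
#' @param response_profiles genes x P matrix of average responses, genes in
#'   the same order as the basis (rownames, if present, are checked).
#' @param basis an `eigengene_basis`.
#' @param selected causal eigengene indices (rows of `B`).
#' @param meta data.frame with one row per column: `column`, `gene`, `sign`
#'   (`"KD"` or `"OE"`).
#' @return Object of class `perturbation_library`: `B` (r x P),
#'   `perturbation_meta`, `response_correlations`.
#' @export
build_library <- function(response_profiles, basis, selected, meta) {
  stopifnot(inherits(basis, "eigengene_basis"))
  rp <- as.matrix(response_profiles)
  if (nrow(rp) != nrow(basis$U)) {
    g1 <- rownames(rp); g2 <- rownames(basis$U)
    extra <- union(setdiff(g1, g2), setdiff(g2, g1))
    stopf("gene set mismatch between responses and basis (%d genes differ: %s)",
          length(extra), paste(utils::head(extra, 5), collapse = ", "))
  }
  if (nrow(meta) != ncol(rp)) stopf("metadata rows must match response columns")
  if (!all(meta$sign %in% c("KD", "OE"))) stopf("sign must be 'KD' or 'OE'")
  B <- crossprod(basis$U[, selected, drop = FALSE], rp)
  zero_cols <- colSums(B^2) < 1e-20
  if (any(zero_cols))
    warnf("%d response column(s) are orthogonal to all selected eigengenes",
          sum(zero_cols))
  cors <- suppressWarnings(stats::cor(rp))
  cors[!is.finite(cors)] <- 0
  diag(cors) <- 1
  structure(list(B = B, perturbation_meta = meta,
                 response_correlations = cors,
                 selected_eigengenes = selected),
            class = "perturbation_library")
}

#' Residual steering distance
#'
#' Euclidean norm of `x_to - x_from - B u`.
#'
#' @param x_from,x_to state vectors in causal-eigengene coordinates.
#' @param B r x P response matrix (or a `perturbation_library`).
#' @param u weight vector in [0,1]^P.
#' @return Non-negative scalar.
#' @export
transition_distance <- function(x_from, x_to, B, u) {
  if (inherits(B, "perturbation_library")) B <- B$B
  sqrt(sum((x_to - x_from - as.numeric(B %*% u))^2))
}

#' Coefficient of determination of a steering solution
#'
#' `R^2 = 1 - D(u)/D(0)`: the fraction of the baseline-to-variant distance
#' closed by the perturbation combination `u` (at most 1; 0.5 means the
#' distance has been halved).
#'
#' @inheritParams transition_distance
#' @return Scalar `<= 1`.
#' @export
steering_r_squared <- function(x_from, x_to, B, u) {
  d0 <- sqrt(sum((x_to - x_from)^2))
  if (d0 == 0) stopf("degenerate pair: identical endpoints (D(0) = 0)")
  1 - transition_distance(x_from, x_to, B, u) / d0
}

#' Solve one bounded L1-penalized steering problem
#'
#' Minimizes `D(u) + lambda * sum(u)` over the box `[0,1]^P` with L-BFGS-B
#' from the fixed start `u = 0`. The objective is convex (norm of an affine
#' map plus a linear term), so the box-constrained quasi-Newton solution is
#' global.
#'
#' @param x_from,x_to state vectors in causal-eigengene coordinates.
#' @param B r x P response matrix or `perturbation_library`.
#' @param lambda L1 weight (>= 0).
#' @return Object of class `transition_solution`: `u`, `r_squared`, `lambda`,
#'   `objective`, `converged`.
#' @export
solve_transition <- function(x_from, x_to, B, lambda = 0) {
  if (inherits(B, "perturbation_library")) B <- B$B
  delta <- x_to - x_from
  d0 <- sqrt(sum(delta^2))
  if (d0 == 0) stopf("degenerate pair: identical endpoints (D(0) = 0)")
  P <- ncol(B)
  fn <- function(u) {
    r <- delta - as.numeric(B %*% u)
    sqrt(sum(r^2)) + lambda * sum(u)
  }
  gr <- function(u) {
    r <- delta - as.numeric(B %*% u)
    nr <- sqrt(sum(r^2))
    g <- if (nr > 1e-12) -as.numeric(crossprod(B, r)) / nr else numeric(P)
    g + lambda
  }
  opt <- optim(rep(0, P), fn, gr, method = "L-BFGS-B",
               lower = rep(0, P), upper = rep(1, P),
               control = list(maxit = 1000, factr = 10, pgtol = 1e-12))
  u <- pmin(pmax(opt$par, 0), 1)
  f_cur <- fn(u)
  # When an exact fit is attainable the optimum of D + lambda * sum(u) is
  # the minimum-L1 point of the feasible polytope {u in box : Bu = delta},
  # a vertex the quasi-Newton iteration cannot reach along the kink of the
  # norm (it stalls on the feasible manifold with spurious small weights).
  # Refine through that linear program (tiny ridge makes it a strictly
  # convex QP); keep the refinement only if the true objective improves.
  if (transition_distance(x_from, x_to, B, u) < 0.05 * d0) {
    refined <- tryCatch({
      eps <- 1e-9
      Amat <- cbind(t(B), diag(P), -diag(P))
      bvec <- c(delta, rep(0, P), rep(-1, P))
      qp <- quadprog::solve.QP(Dmat = diag(eps, P), dvec = rep(-lambda, P),
                               Amat = Amat, bvec = bvec, meq = nrow(B))
      pmin(pmax(qp$solution, 0), 1)
    }, error = function(e) NULL)
    if (!is.null(refined)) {
      cand <- ifelse(refined < 1e-10, 0, refined)
      if (fn(cand) <= f_cur) { u <- cand; f_cur <- fn(cand) }
    }
  }
  # drop solver crumbs whose penalty is never recouped
  for (cut in c(1e-4, 1e-3)) {
    cand <- ifelse(u <= cut, 0, u)
    if (fn(cand) <= f_cur + 1e-12) { u <- cand; f_cur <- fn(cand) }
  }
  structure(list(u = u,
                 r_squared = steering_r_squared(x_from, x_to, B, u),
                 lambda = lambda, objective = fn(u),
                 converged = opt$convergence == 0,
                 message = opt$message),
            class = "transition_solution")
}

#' Sparsest acceptable solution along a lambda grid
#'
#' Solves the steering problem at each `lambda`, descending from the largest,
#' and returns the solution for the largest `lambda` whose `R^2` strictly
#' exceeds `r2_min` (the sparsest acceptable solution). Returns `NULL`
#' (a rejection) when no grid point qualifies.
#'
#' @inheritParams solve_transition
#' @param lambda_grid ascending positive grid (default 25 log-spaced values
#'   in [1e-4, 10]).
#' @param r2_min acceptance bound on `R^2` (default 0.99, strict).
#' @return A `transition_solution`, or `NULL` if the pair is rejected.
#' @export
lambda_sweep <- function(x_from, x_to, B, lambda_grid = default_lambda_grid(),
                         r2_min = 0.99) {
  if (length(lambda_grid) == 0) stopf("empty lambda grid")
  lambda_grid <- sort(lambda_grid)
  for (lam in rev(lambda_grid)) {
    sol <- solve_transition(x_from, x_to, B, lam)
    if (sol$r_squared > r2_min) return(sol)
  }
  NULL
}

#' Default lambda grid
#' @param n number of points (default 25).
#' @param lo,hi grid bounds (default 1e-4 and 10).
#' @return Ascending numeric vector, log-spaced.
#' @export
default_lambda_grid <- function(n = 25, lo = 1e-4, hi = 10) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Binarize a weight vector
#'
#' Entry 1 iff `u > threshold` (strict); the binarized rows of accepted
#' solutions form the bipartite occurrence matrix `A`.
#'
#' @param u weight vector in [0,1].
#' @param threshold occurrence threshold (default 0.01).
#' @return Integer 0/1 vector.
#' @export
binarize_u <- function(u, threshold = 0.01) as.integer(u > threshold)

#' Sweep random baseline-variant pairs in both directions
#'
#' Samples `n_pairs` (baseline, variant) index pairs uniformly with
#' replacement, runs [lambda_sweep()] for each sampled pair in each requested
#' direction (forward: baseline to variant; reverse: variant to baseline),
#' binarizes the accepted weight vectors, and stacks them into the occurrence
#' matrix `A`.
#'
#' @param baseline_states,variant_states matrices with one state per row, in
#'   causal-eigengene coordinates.
#' @param B r x P response matrix or `perturbation_library`.
#' @param n_pairs number of sampled pairs per direction (default 2500).
#' @param directions subset of `c("forward", "reverse")`.
#' @param lambda_grid forwarded to [lambda_sweep()].
#' @param r2_min acceptance bound (default 0.99).
#' @param threshold binarization threshold (default 0.01).
#' @param seed integer seed for pair sampling.
#' @return Object of class `pair_sweep_result`: `A` (accepted rows x P),
#'   `directions` (per row), `lambda`, `r_squared` (per row),
#'   `n_perturbations` (per-row counts; histogram data), `rejected` count.
#' @export
sweep_pairs <- function(baseline_states, variant_states, B, n_pairs = 2500,
                        directions = c("forward", "reverse"),
                        lambda_grid = default_lambda_grid(), r2_min = 0.99,
                        threshold = 0.01, seed = 1L) {
  if (inherits(B, "perturbation_library")) B <- B$B
  directions <- match.arg(directions, several.ok = TRUE)
  nb <- nrow(baseline_states); nv <- nrow(variant_states)
  if (nb < 1 || nv < 1) stopf("need at least one state per cluster")
  P <- ncol(B)
  with_seed(seed, {
    ib <- sample.int(nb, n_pairs, replace = TRUE)
    iv <- sample.int(nv, n_pairs, replace = TRUE)
    rows <- list(); dir_tag <- character(0)
    lam <- numeric(0); r2 <- numeric(0); rejected <- 0L
    for (p in seq_len(n_pairs)) {
      xb <- baseline_states[ib[p], ]; xv <- variant_states[iv[p], ]
      for (dr in directions) {
        sol <- if (dr == "forward") lambda_sweep(xb, xv, B, lambda_grid, r2_min)
               else lambda_sweep(xv, xb, B, lambda_grid, r2_min)
        if (is.null(sol)) { rejected <- rejected + 1L; next }
        rows[[length(rows) + 1L]] <- binarize_u(sol$u, threshold)
        dir_tag <- c(dir_tag, dr)
        lam <- c(lam, sol$lambda); r2 <- c(r2, sol$r_squared)
      }
    }
    if (length(rows) == 0) stopf("zero accepted pairs")
    A <- do.call(rbind, rows)
    structure(list(A = A, directions = dir_tag, lambda = lam, r_squared = r2,
                   n_perturbations = rowSums(A), rejected = rejected,
                   threshold = threshold, r2_min = r2_min),
              class = "pair_sweep_result")
  })
}

#' Steer between cluster centroids
#'
#' Average-state mode: a single [lambda_sweep()] between the baseline and
#' variant cluster means, returning the solution together with the per-column
#' weights ranked for inspection.
#'
#' @inheritParams sweep_pairs
#' @param direction `"forward"` or `"reverse"`.
#' @return The accepted `transition_solution` (or `NULL` if rejected) with an
#'   added `ranking` data.frame of columns sorted by weight.
#' @export
steer_centroids <- function(baseline_states, variant_states, B,
                            direction = c("forward", "reverse"),
                            lambda_grid = default_lambda_grid(),
                            r2_min = 0.99) {
  direction <- match.arg(direction)
  meta <- if (inherits(B, "perturbation_library")) B$perturbation_meta else NULL
  if (inherits(B, "perturbation_library")) B <- B$B
  cb <- colMeans(baseline_states); cv <- colMeans(variant_states)
  sol <- if (direction == "forward") lambda_sweep(cb, cv, B, lambda_grid, r2_min)
         else lambda_sweep(cv, cb, B, lambda_grid, r2_min)
  if (is.null(sol)) return(NULL)
  ord <- order(-sol$u)
  sol$ranking <- data.frame(
    column = if (is.null(meta)) ord else meta$column[ord],
    gene = if (is.null(meta)) NA_character_ else meta$gene[ord],
    sign = if (is.null(meta)) NA_character_ else meta$sign[ord],
    weight = sol$u[ord])
  sol
}
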