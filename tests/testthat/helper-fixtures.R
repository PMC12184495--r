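# Shared fixtures, built in code and memoised for the session.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# small planted two-cluster dataset + basis + projection
small_planted <- function() memo("small_planted", {
  cfg <- syn_config(n_genes = 120, n_baseline = 60, n_variant = 60,
                    latent_rank = 6, n_causal = 1, seed = 3)
  g <- generate_expression(cfg)
  basis <- compute_basis(g$expr)
  proj <- project_eigengenes(g$expr, basis, d = 30)
  list(cfg = cfg, expr = g$expr, truth = g$truth, basis = basis, proj = proj)
})

# d = 8 summary-statistics fixture with a PD correlation matrix
fixture_d8 <- function() memo("fixture_d8", {
  set.seed(11)
  m <- 40; d <- 8
  X <- matrix(rnorm(m * d), m, d)
  y <- as.integer(stats::plogis(2 * X[, 3]) > runif(m))
  fit <- fit_logistic(X, y)
  list(X = X, y = y, fit = fit,
       xi = z_value(X, fit$zeta), R = correlation_matrix(X, fit$sigma2))
})

# tiny trained conditional VAE (intentionally undersized; config warns)
tiny_cvae <- function() memo("tiny_cvae", {
  cfg <- syn_config(n_genes = 40, n_baseline = 25, n_variant = 25,
                    latent_rank = 4, n_causal = 1, class_shift = 5, seed = 9)
  g <- generate_expression(cfg)
  tc <- suppressWarnings(cvae_config(latent_dim = 4, hidden_sizes = c(24, 12),
                                     epochs = 120, batch_size = 25, seed = 2))
  model <- cvae_train(g$expr, tc)
  list(expr = g$expr, truth = g$truth, config = tc, model = model)
})

# best single-threshold accuracy of a score vector against binary labels
threshold_accuracy <- function(score, labels) {
  cuts <- sort(unique(score))
  best <- 0
  for (t in cuts) {
    acc <- max(mean((score > t) == (labels == 1)),
               mean((score <= t) == (labels == 1)))
    best <- max(best, acc)
  }
  best
}

# two-stage grid oracle for the convex steering objective (1e-3 resolution)
grid_oracle <- function(x_from, x_to, B, lambda, coarse = 1e-2, fine = 1e-3) {
  P <- ncol(B)
  obj_batch <- function(U) {
    resid <- matrix(x_to - x_from, nrow(B), ncol(U)) - B %*% U
    sqrt(colSums(resid^2)) + lambda * colSums(U)
  }
  grids <- rep(list(seq(0, 1, by = coarse)), P)
  U <- t(as.matrix(expand.grid(grids)))
  v <- obj_batch(U)
  u0 <- U[, which.min(v)]
  grids <- lapply(u0, function(ui)
    seq(max(0, ui - 2 * coarse), min(1, ui + 2 * coarse), by = fine))
  U <- t(as.matrix(expand.grid(grids)))
  v <- obj_batch(U)
  list(objective = min(v), u = U[, which.min(v)])
}
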