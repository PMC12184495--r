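test_that("library projection maps responses onto selected eigengenes", {
  set.seed(12)
  Y <- matrix(rnorm(15 * 25), 15, 25)
  b <- compute_basis(Y)
  meta <- data.frame(column = c("p1", "p2", "p3"),
                     gene = c("GA", "GB", "GB"),
                     sign = c("KD", "OE", "OE"))
  # column 1 = eigengene 1; column 2 orthogonal to the selected set;
  # column 3 duplicates column 2
  ortho <- b$U[, 10]
  rp <- cbind(b$U[, 1], ortho, ortho)
  expect_warning(lib <- build_library(rp, b, selected = 1:4, meta),
                 "orthogonal")
  expect_equal(lib$B[, 1], c(1, 0, 0, 0), tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(abs(lib$B[, 2])), 1e-10)
  expect_equal(lib$response_correlations[2, 3], 1.0)
  expect_error(build_library(rp[1:10, ], b, 1:4, meta), "mismatch")
  expect_error(build_library(rp, b, 1:4, transform(meta, sign = "up")),
               "KD")
})

test_that("distance and R^2 follow Eqs for the residual norm", {
  set.seed(13)
  B <- matrix(rnorm(6 * 4), 6, 4)
  x0 <- rnorm(6); x1 <- rnorm(6)
  expect_equal(transition_distance(x0, x1, B, rep(0, 4)),
               sqrt(sum((x1 - x0)^2)))
  u <- runif(4)
  x1b <- x0 + as.numeric(B %*% u)
  expect_lt(transition_distance(x0, x1b, B, u), 1e-12)
  # direct numeric oracle on random instances
  for (i in 1:5) {
    ur <- runif(4)
    expect_equal(transition_distance(x0, x1, B, ur),
                 norm(x1 - x0 - B %*% ur, "2"))
  }
  expect_equal(steering_r_squared(x0, x1b, B, u), 1.0)
  expect_equal(steering_r_squared(x0, x1, B, rep(0, 4)), 0.0)
  # residual exactly halved -> R^2 = 0.5
  Bh <- cbind((x1 - x0) / 2)
  expect_equal(steering_r_squared(x0, x1, Bh, 1), 0.5)
  expect_error(steering_r_squared(x0, x0, B, rep(0, 4)), "degenerate")
})

test_that("solver finds the matching column and respects the L1 shutoff", {
  set.seed(15)
  x0 <- rnorm(5); diff <- rnorm(5)
  x1 <- x0 + diff
  # one column equals the difference, others orthogonal to it
  o1 <- diff / sqrt(sum(diff^2))
  Qf <- qr.Q(qr(cbind(o1, matrix(rnorm(10), 5, 2))))
  B <- cbind(diff, Qf[, 2], Qf[, 3])
  sol <- solve_transition(x0, x1, B, lambda = 1e-6)
  expect_gte(sol$u[1], 0.99)
  expect_lte(max(sol$u[2:3]), 1e-3)
  expect_gte(sol$r_squared, 0.99)
  expect_true(all(sol$u >= 0 & sol$u <= 1))
  # stored R^2 matches an independent recomputation
  expect_equal(sol$r_squared, steering_r_squared(x0, x1, B, sol$u),
               tolerance = 1e-8)
  # large lambda shuts all weights off (subgradient bound)
  lam_big <- 2 * max(abs(crossprod(B, diff)))
  sol0 <- solve_transition(x0, x1, B, lambda = lam_big)
  expect_equal(sol0$u, rep(0, 3), tolerance = 1e-8)
})

test_that("solver matches the 1e-3 grid oracle at P <= 3", {
  # the objective is convex, so the two-stage grid is an exact 1e-3 oracle
  set.seed(16)
  for (P in 2:3) {
    B <- matrix(rnorm(4 * P), 4, P)
    x0 <- rnorm(4); x1 <- rnorm(4) * 2
    lam <- 0.05
    sol <- solve_transition(x0, x1, B, lambda = lam)
    gr <- grid_oracle(x0, x1, B, lam)
    expect_lte(sol$objective, gr$objective + 1e-6)
    expect_lt(gr$objective - sol$objective, 0.01)
  }
})

test_that("penalized optima are monotone in lambda", {
  set.seed(17)
  ts <- generate_transition_set(r = 8, P = 15, n_baseline = 4, n_variant = 4,
                                k_active = 4, seed = 6)
  grid <- default_lambda_grid(10, 1e-4, 5)
  objs <- vapply(grid, function(l)
    solve_transition(ts$baseline_states[1, ], ts$variant_states[2, ],
                     ts$B, l)$objective, numeric(1))
  expect_true(all(diff(objs) >= -1e-8))
})

test_that("lambda sweep accepts feasible pairs and rejects hopeless ones", {
  ts <- generate_transition_set(r = 8, P = 20, n_baseline = 5, n_variant = 5,
                                k_active = 5, seed = 7)
  sol <- lambda_sweep(ts$baseline_states[1, ], ts$variant_states[1, ], ts$B)
  expect_false(is.null(sol))
  expect_gt(sol$r_squared, 0.99)
  # B = 0: R^2 = 0 at every lambda
  expect_null(lambda_sweep(ts$baseline_states[1, ], ts$variant_states[1, ],
                           matrix(0, 8, 20)))
  expect_error(lambda_sweep(ts$baseline_states[1, ], ts$variant_states[1, ],
                            ts$B, lambda_grid = numeric(0)), "empty")
})

test_that("support size shrinks along the lambda path", {
  ts <- generate_transition_set(r = 10, P = 25, n_baseline = 6, n_variant = 6,
                                k_active = 6, seed = 8)
  grid <- default_lambda_grid(12, 1e-4, 2)
  steps <- 0L; viol <- 0L
  for (inst in 1:6) {
    i <- ((inst - 1) %% 6) + 1
    nz <- vapply(grid, function(l)
      sum(binarize_u(solve_transition(ts$baseline_states[i, ],
                                      ts$variant_states[i, ], ts$B, l)$u)),
      numeric(1))
    dd <- diff(nz)
    steps <- steps + length(dd)
    viol <- viol + sum(dd > 0)
  }
  expect_lte(viol / steps, 0.05)
})

test_that("pair sweeps accept planted pairs and are reproducible", {
  ts <- generate_transition_set(r = 12, P = 30, n_baseline = 10,
                                n_variant = 10, k_active = 6, seed = 9)
  sw <- sweep_pairs(ts$baseline_states, ts$variant_states, ts$B,
                    n_pairs = 40, directions = "forward", seed = 10)
  expect_gte(nrow(sw$A) / 40, 0.95)
  expect_true(all(sw$A %in% c(0L, 1L)))
  expect_true(all(sw$r_squared > 0.99))
  expect_identical(sw$n_perturbations, rowSums(sw$A))
  sw2 <- sweep_pairs(ts$baseline_states, ts$variant_states, ts$B,
                     n_pairs = 40, directions = "forward", seed = 10)
  expect_identical(sw$A, sw2$A)
})

test_that("forward and reverse directions select different columns", {
  # planted asymmetric library: forward displacement spanned by columns 1-3,
  # the reverse displacement by columns 4-6 (responses not antialigned)
  set.seed(18)
  r <- 8
  Bf <- matrix(rnorm(r * 3), r, 3)
  uf <- c(0.5, 0.4, 0.6)
  delta <- as.numeric(Bf %*% uf)
  # column 4 alone spans -delta at weight 0.6; columns 5-6 are distractors
  Br <- cbind(-delta / 0.6, matrix(rnorm(r * 2), r, 2))
  B <- cbind(Bf, Br, matrix(rnorm(r * 4), r, 4))
  base <- rnorm(r)
  baseline_states <- rbind(base, base + 1e-3 * rnorm(r))
  variant_states <- rbind(base + delta, base + delta + 1e-3 * rnorm(r))
  sw <- sweep_pairs(baseline_states, variant_states, B, n_pairs = 10,
                    seed = 11)
  fwd <- which(colSums(sw$A[sw$directions == "forward", , drop = FALSE]) > 0)
  rev <- which(colSums(sw$A[sw$directions == "reverse", , drop = FALSE]) > 0)
  jac <- length(intersect(fwd, rev)) / length(union(fwd, rev))
  expect_lt(jac, 1)
})

test_that("binarization is a strict threshold", {
  expect_identical(binarize_u(rep(0, 4)), rep(0L, 4))
  expect_identical(binarize_u(rep(1, 4)), rep(1L, 4))
  expect_identical(binarize_u(c(0.005, 0.02), 0.01), c(0L, 1L))
  expect_identical(binarize_u(c(1e-9, 0.5), 0), c(1L, 1L))
})

test_that("centroid steering ranks perturbations", {
  ts <- generate_transition_set(r = 8, P = 20, n_baseline = 6, n_variant = 6,
                                k_active = 5, seed = 12)
  sol <- steer_centroids(ts$baseline_states, ts$variant_states, ts$B)
  expect_false(is.null(sol))
  expect_gt(sol$r_squared, 0.99)
  expect_identical(nrow(sol$ranking), 20L)
  expect_true(all(diff(sol$ranking$weight) <= 0))
})
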