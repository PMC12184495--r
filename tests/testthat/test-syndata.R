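test_that("config invariants are enforced", {
  expect_error(syn_config(latent_rank = 0), "positive integer")
  expect_error(syn_config(n_causal = 5, latent_rank = 3), "n_causal")
  expect_error(syn_config(noise_sd = 0), "noise_sd")
  expect_error(syn_config(latent_rank = 50, n_genes = 20, n_baseline = 10,
                          n_variant = 10), "latent_rank")
})

test_that("generated expression is deterministic with exact label balance", {
  cfg <- syn_config(n_genes = 60, n_baseline = 13, n_variant = 17,
                    latent_rank = 4, n_causal = 2, seed = 5)
  g1 <- generate_expression(cfg)
  g2 <- generate_expression(cfg)
  expect_identical(g1$expr$values, g2$expr$values)
  expect_identical(g1$truth$class_mean_delta, g2$truth$class_mean_delta)
  expect_identical(sum(g1$expr$labels == 0), 13L)
  expect_identical(sum(g1$expr$labels == 1), 17L)
  # planted directions are orthonormal
  QtQ <- crossprod(g1$truth$directions)
  expect_lt(max(abs(QtQ - diag(4))), 1e-10)
})

test_that("class_shift = 0 gives a null first-direction score difference", {
  # Monte-Carlo under the null: the two-sample t-test on scores along the
  # first planted direction should be non-significant at alpha = 0.01 in at
  # least 95% of seeds
  nonsig <- vapply(1:100, function(s) {
    cfg <- syn_config(n_genes = 40, n_baseline = 15, n_variant = 15,
                      latent_rank = 3, n_causal = 1, class_shift = 0, seed = s)
    g <- generate_expression(cfg)
    sc <- as.numeric(g$expr$values %*% g$truth$causal_dirs[, 1])
    stats::t.test(sc[g$expr$labels == 1], sc[g$expr$labels == 0])$p.value > 0.01
  }, logical(1))
  expect_gte(mean(nonsig), 0.95)
})

test_that("noiseless well-shifted classes are linearly separable", {
  cfg <- syn_config(n_genes = 50, n_baseline = 20, n_variant = 20,
                    latent_rank = 3, n_causal = 1, class_shift = 5,
                    noise_sd = 1e-9, seed = 2)
  g <- generate_expression(cfg)
  fit <- fit_logistic(g$expr$values, g$expr$labels)
  expect_equal(fit$accuracy, 1.0)
})

test_that("perturbation library plants an exactly feasible steering solution", {
  sp <- small_planted()
  lib <- generate_perturbation_library(sp$cfg, sp$basis, sp$truth)
  expect_identical(ncol(lib$B), sp$cfg$n_perturbations)
  expect_identical(nrow(lib$perturbation_meta), ncol(lib$B))
  sel <- lib$selected_eigengenes
  target <- as.numeric(crossprod(sp$basis$U[, sel, drop = FALSE],
                                 sp$truth$class_mean_delta))
  expect_lt(max(abs(as.numeric(lib$B %*% lib$planted_u) - target)), 1e-10)
  # gene-space feasibility of the designated subset, by construction
  recon <- as.numeric(lib$response_profiles %*% lib$planted_u)
  expect_lt(max(abs(recon - sp$truth$class_mean_delta)), 1e-10)
})

test_that("library sign composition follows frac_overexpression", {
  sp <- small_planted()
  cfg0 <- syn_config(n_genes = 120, n_baseline = 60, n_variant = 60,
                     latent_rank = 6, n_causal = 1, frac_overexpression = 0,
                     seed = 3)
  lib0 <- generate_perturbation_library(cfg0, sp$basis, sp$truth)
  expect_true(all(lib0$perturbation_meta$sign == "KD"))
  cfg1 <- syn_config(n_genes = 120, n_baseline = 60, n_variant = 60,
                     latent_rank = 6, n_causal = 1, frac_overexpression = 0.5,
                     seed = 3)
  lib1 <- generate_perturbation_library(cfg1, sp$basis, sp$truth)
  expect_identical(sum(lib1$perturbation_meta$sign == "OE"), 20L)
})

test_that("transition sets plant box-feasible pair solutions", {
  ts <- generate_transition_set(r = 10, P = 25, n_baseline = 8, n_variant = 8,
                                k_active = 5, seed = 4)
  # direct evaluation of the planted u for every forward pair
  for (i in 1:8) for (j in 1:8) {
    u <- ts$u_delta + ts$coef_variant[i, ] - ts$coef_baseline[j, ]
    expect_true(all(u >= 0 & u <= 1))
    resid <- ts$variant_states[i, ] - ts$baseline_states[j, ] -
      as.numeric(ts$B %*% u)
    expect_lt(sqrt(sum(resid^2)), 1e-8)
  }
  # and via the optimizer on a sampled pair
  sol <- solve_transition(ts$baseline_states[3, ], ts$variant_states[5, ],
                          ts$B, lambda = 0)
  expect_lt(transition_distance(ts$baseline_states[3, ], ts$variant_states[5, ],
                                ts$B, sol$u), 1e-6)
  expect_identical(generate_transition_set(r = 10, P = 25, n_baseline = 8,
                                           n_variant = 8, k_active = 5,
                                           seed = 4)$B, ts$B)
})

test_that("bipartite generator honors density, boosts, and determinism", {
  expect_error(generate_bipartite(10, 5, 0.5, planted_pairs = list(c(1, 9))),
               "out of range")
  expect_true(all(generate_bipartite(20, 6, 1, seed = 1) == 1))
  A1 <- generate_bipartite(200, 12, 0.3, seed = 8)
  expect_identical(A1, generate_bipartite(200, 12, 0.3, seed = 8))

  # boost = 0: empirical pair co-occurrence within 3 binomial SDs of density^2
  A <- generate_bipartite(2000, 20, 0.2, seed = 2)
  f <- crossprod(A) / 2000
  se <- sqrt(0.04 * 0.96 / 2000)
  within <- abs(f[upper.tri(f)] - 0.04) <= 3 * se
  expect_gte(mean(within), 0.95)

  # planted pair: f above 0.3 for boost 0.4 at density 0.1
  Ab <- generate_bipartite(2000, 10, 0.1, planted_pairs = list(c(2, 7)),
                           boost = 0.4, seed = 3)
  f27 <- mean(Ab[, 2] * Ab[, 7])
  expect_gt(f27, 0.3)
})

test_that("count generator and dataset writer feed the curation path", {
  g <- generate_counts(n_genes = 80, n_samples = 12, seed = 6)
  expect_true(all(g$counts$values >= 0))
  expect_identical(g$counts$values, generate_counts(n_genes = 80,
                                                    n_samples = 12,
                                                    seed = 6)$counts$values)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(dir, n_genes = 80, n_samples = 12, seed = 6)
  expect_true(all(file.exists(paths)))
  back <- read_counts_tsv(paths["counts"], paths["labels"])
  expect_equal(back$values, g$counts$values, ignore_attr = TRUE)
  expect_identical(back$labels, g$counts$labels)
})
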