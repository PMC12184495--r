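test_that("unit scaling maps ranges to [0,1] and inverts exactly", {
  m <- cbind(a = c(0, 15, 7.5), b = c(2, 2, 2), c = c(-4, 1, 6))
  sc <- scale_to_unit(m)
  expect_equal(sc$values[, "a"], c(0, 1, 0.5), ignore_attr = TRUE)
  expect_true(all(sc$values[, "b"] == 0.5))
  expect_identical(unname(sc$bounds$constant), c(FALSE, TRUE, FALSE))
  back <- inverse_scale(sc$values, sc$bounds)
  expect_lt(max(abs(back - m)), 1e-10)
})

test_that("loss terms have their closed forms and stay non-negative", {
  # crafted forward state: exercise the loss parts directly
  n <- 3; L <- 4
  mk_fw <- function(mu, lv) {
    list(mu = mu, lv = lv, xhat = matrix(0.5, n, 2),
         logits = matrix(0, n, 2))
  }
  w <- c(recon = 1, kl = 1, class = 1)
  # posterior = prior -> kl = 0
  parts0 <- eigensteer:::cvae_loss_parts(
    mk_fw(matrix(0, n, L), matrix(0, n, L)),
    matrix(0.5, n, 2), encode_labels(c(0, 1, 0)), w)
  expect_equal(unname(parts0["kl"]), 0)
  # unit variance, mean mu -> kl = mean(mu^2)/2 per dimension
  mu <- matrix(rnorm(n * L), n, L)
  parts1 <- eigensteer:::cvae_loss_parts(
    mk_fw(mu, matrix(0, n, L)),
    matrix(0.5, n, 2), encode_labels(c(0, 1, 0)), w)
  expect_equal(unname(parts1["kl"]), mean(mu^2) / 2)
  # recon at its minimum for x = xhat = 0.5 is the entropy -log(0.5)
  expect_equal(unname(parts1["recon"]), -log(0.5))
  # uniform logits -> class loss log(2)
  expect_equal(unname(parts1["class"]), log(2))
  expect_true(all(parts1 >= 0))
})

test_that("backward pass matches central finite differences", {
  set.seed(14)
  G <- 7; n <- 4
  cfg <- suppressWarnings(cvae_config(latent_dim = 3, hidden_sizes = c(5, 4),
                                      epochs = 500, batch_size = 50, seed = 1))
  par <- eigensteer:::cvae_init(G, cfg)
  x <- matrix(runif(n * G, 0.05, 0.95), n, G)
  yh <- encode_labels(c(0, 1, 1, 0))
  eps <- matrix(rnorm(n * 3), n, 3)
  w <- c(recon = 1.3, kl = 0.7, class = 1.1)
  loss_at <- function(par) {
    fw <- eigensteer:::cvae_forward(par, x, yh, eps)
    unname(eigensteer:::cvae_loss_parts(fw, x, yh, w)["total"])
  }
  fw <- eigensteer:::cvae_forward(par, x, yh, eps)
  gr <- eigensteer:::cvae_backward(par, fw, x, yh, w)
  h <- 1e-6
  for (nm in names(par)) {
    idx <- sample(length(par[[nm]]), min(4, length(par[[nm]])))
    for (i in idx) {
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("training reduces the loss deterministically", {
  tc <- tiny_cvae()
  tr <- tc$model$trace
  expect_true(all(is.finite(as.matrix(tr[, -1]))))
  expect_lt(tr$total[nrow(tr)], tr$total[1])
  expect_true(all(tr$kl >= 0) && all(tr$recon >= 0) && all(tr$class >= 0))
  # same seed, same data -> identical loss trace
  m2 <- cvae_train(tc$expr, tc$config)
  expect_identical(m2$trace, tc$model$trace)
  expect_identical(m2$params$W1, tc$model$params$W1)
})

test_that("encoding returns finite posterior means, one per sample", {
  tc <- tiny_cvae()
  emb <- cvae_encode(tc$model, tc$expr)
  expect_identical(nrow(emb$coordinates), nrow(tc$expr$values))
  expect_true(all(is.finite(emb$coordinates)))
  # duplicate inputs embed identically
  dup <- tc$expr$values[c(1, 1), ]
  e2 <- cvae_encode(tc$model, dup, labels = c(0, 0))
  expect_identical(e2$coordinates[1, ], e2$coordinates[2, ])
  expect_error(cvae_encode(tc$model, tc$expr$values[, 1:10], labels = tc$expr$labels),
               "gene count mismatch")
})

test_that("decoded profiles stay inside the training bounds", {
  tc <- tiny_cvae()
  z <- matrix(rnorm(20 * tc$config$latent_dim, sd = 3), 20)
  dec <- cvae_decode(tc$model, z, rep(c(0, 1), 10))
  ok <- !tc$model$bounds$constant
  expect_true(all(t(dec[, ok]) >= tc$model$bounds$min[ok] - 1e-9))
  expect_true(all(t(dec[, ok]) <= tc$model$bounds$max[ok] + 1e-9))
})

test_that("latent KDE sampling is balanced, seeded, and centered per class", {
  tc <- tiny_cvae()
  emb <- cvae_encode(tc$model, tc$expr)
  gen <- sample_profiles(tc$model, emb, n_per_class = 30, seed = 4)
  expect_identical(as.integer(table(gen$labels)), c(30L, 30L))
  gen2 <- sample_profiles(tc$model, emb, n_per_class = 30, seed = 4)
  expect_identical(gen$values, gen2$values)

  # degenerate KDE: bandwidth -> 0 with duplicated embedded points decodes
  # those exact points
  two <- structure(list(coordinates = emb$coordinates[c(1, 1, 2, 2), ],
                        labels = c(0L, 0L, 1L, 1L)),
                   class = "latent_embedding")
  g0 <- sample_profiles(tc$model, two, n_per_class = 5, bandwidth = 1e-12,
                        seed = 1)
  dec0 <- cvae_decode(tc$model, emb$coordinates[1, , drop = FALSE], 0L)
  expect_equal(g0$values[1, ], dec0[1, ], tolerance = 1e-8, ignore_attr = TRUE)

  one <- structure(list(coordinates = emb$coordinates[1:2, , drop = FALSE],
                        labels = c(0L, 1L)), class = "latent_embedding")
  expect_error(sample_latent(one, 5), "fewer than 2")

  # per-class mean of the latent draws within 3 SE of the embedded mean
  z <- sample_latent(emb, n_per_class = 1000, bandwidth = 0.2, seed = 7)
  pts0 <- emb$coordinates[emb$labels == 0, , drop = FALSE]
  se <- sqrt((apply(pts0, 2, function(v) mean((v - mean(v))^2)) + 0.04) / 1000)
  expect_true(all(abs(colMeans(z$baseline) - colMeans(pts0)) <= 3 * se + 1e-9))
})

test_that("retention curve reproduces its analytic endpoints", {
  p <- runif(200)
  expect_equal(retention_curve(p, p)$auroc, 1.0)
  expect_equal(retention_curve(p, -p)$auroc, 0.0)
  set.seed(31)
  null_auroc <- replicate(100, retention_curve(p, sample(p))$auroc)
  expect_lt(abs(mean(null_auroc) - 0.5), 0.05)
})

test_that("auroc_retention ties the t-test ranking to the curve", {
  tc <- tiny_cvae()
  expect_equal(auroc_retention(tc$expr, tc$expr)$auroc, 1.0)
  expect_error(auroc_retention(tc$expr,
                               expression_set(tc$expr$values[, 1:10],
                                              tc$expr$labels)),
               "gene sets")
})

test_that("checkpoints round-trip through the JSON container", {
  tc <- tiny_cvae()
  p <- tempfile(fileext = ".json")
  save_cvae(tc$model, p)
  back <- load_cvae(p)
  expect_equal(back$params, tc$model$params, tolerance = 1e-12)
  expect_identical(back$gene_ids, tc$model$gene_ids)
  emb1 <- cvae_encode(tc$model, tc$expr)
  emb2 <- cvae_encode(back, tc$expr)
  expect_equal(emb1$coordinates, emb2$coordinates, tolerance = 1e-10)
})
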