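# Label-conditioned variational autoencoder for phenotype-labeled expression
# profiles. Encoder: [profile, one-hot label] -> 256 -> 128 -> (mu, log-var).
# Decoder: [z, one-hot label] -> 128 -> 256 -> sigmoid(genes). Classifier: a
# single linear map from the latent posterior mean to 2 logits. Implemented
# directly in base R (BLAS matrix ops, hand-derived gradients, Adam); the
# gradient is checked against finite differences in the test suite.

#' Conditional VAE configuration
#'
#' @param latent_dim latent dimensionality (default 16; the latent space is
#'   inspected through its principal components, so > 2 is expected).
#' @param hidden_sizes encoder hidden widths, mirrored by the decoder
#'   (default `c(256, 128)`).
#' @param learning_rate Adam step size (default 1e-4).
#' @param epochs training epochs; the supported range is [500, 1e4]
#'   (values outside it are allowed with a warning).
#' @param batch_size minibatch size; supported range [50, 200] (warned
#'   otherwise, and capped at the sample count during training).
#' @param loss_weights positive weights `c(recon, kl, class)`.
#' @param kde_bandwidth Gaussian-kernel bandwidth for latent sampling
#'   (default 0.2, on raw latent coordinates).
#' @param recon_loss `"bce"` (binary cross-entropy on unit-scaled data,
#'   matching the sigmoid output head) or `"mse"`.
#' @param seed integer seed controlling initialization, shuffling, and the
#'   reparameterization draws.
#' @return List of class `cvae_config`.
#' @export
cvae_config <- function(latent_dim = 16, hidden_sizes = c(256, 128),
                        learning_rate = 1e-4, epochs = 500, batch_size = 50,
                        loss_weights = c(recon = 1, kl = 1, class = 1),
                        kde_bandwidth = 0.2, recon_loss = c("bce", "mse"),
                        seed = 1L) {
  recon_loss <- match.arg(recon_loss)
  if (length(hidden_sizes) != 2) stopf("hidden_sizes must have length 2")
  if (any(loss_weights <= 0)) stopf("loss_weights must be positive")
  if (epochs < 500 || epochs > 1e4)
    warnf("epochs = %d is outside the supported range [500, 1e4]", epochs)
  if (batch_size < 50 || batch_size > 200)
    warnf("batch_size = %d is outside the supported range [50, 200]", batch_size)
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_sizes = as.integer(hidden_sizes),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 loss_weights = stats::setNames(as.numeric(loss_weights),
                                                c("recon", "kl", "class")),
                 kde_bandwidth = kde_bandwidth, recon_loss = recon_loss,
                 seed = as.integer(seed)),
            class = "cvae_config")
}

#' Min-max scale expression to the unit interval
#'
#' Per-gene map to [0, 1] as required by the sigmoid output head. Constant
#' genes are mapped to 0.5 and flagged in the bounds.
#'
#' @param expr [expression_set()] or samples x genes matrix.
#' @return List with `values` (scaled matrix) and `bounds`
#'   (`min`, `max`, `constant` per gene).
#' @export
scale_to_unit <- function(expr) {
  m <- if (inherits(expr, "expression_set")) expr$values else as.matrix(expr)
  lo <- apply(m, 2, min); hi <- apply(m, 2, max)
  const <- hi == lo
  rng <- ifelse(const, 1, hi - lo)
  sc <- sweep(sweep(m, 2, lo), 2, rng, `/`)
  sc[, const] <- 0.5
  list(values = sc, bounds = list(min = lo, max = hi, constant = const))
}

#' Invert the unit scaling
#'
#' @param values unit-scaled samples x genes matrix.
#' @param bounds the `bounds` element from [scale_to_unit()] (constant genes
#'   are restored to their original value).
#' @return Matrix on the original scale.
#' @export
inverse_scale <- function(values, bounds) {
  rng <- ifelse(bounds$constant, 0, bounds$max - bounds$min)
  out <- sweep(sweep(values, 2, rng, `*`), 2, bounds$min, `+`)
  out
}

relu <- function(x) x * (x > 0)

dense_init <- function(n_in, n_out, gain = 2) {
  matrix(rnorm(n_in * n_out, sd = sqrt(gain / n_in)), n_in, n_out)
}

cvae_init <- function(n_genes, cfg) {
  h1 <- cfg$hidden_sizes[1]; h2 <- cfg$hidden_sizes[2]; L <- cfg$latent_dim
  list(W1 = dense_init(n_genes + 2, h1), b1 = numeric(h1),
       W2 = dense_init(h1, h2),          b2 = numeric(h2),
       Wmu = dense_init(h2, L, gain = 1), bmu = numeric(L),
       Wlv = dense_init(h2, L, gain = 1), blv = numeric(L),
       V1 = dense_init(L + 2, h2),       c1 = numeric(h2),
       V2 = dense_init(h2, h1),          c2 = numeric(h1),
       V3 = dense_init(h1, n_genes, gain = 1), c3 = numeric(n_genes),
       Wc = dense_init(L, 2, gain = 1),  bc = numeric(2))
}

# forward pass; eps = NULL uses the posterior mean (z = mu)
cvae_forward <- function(par, x, yh, eps = NULL) {
  h1 <- relu(sweep(cbind(x, yh) %*% par$W1, 2, par$b1, `+`))
  h2 <- relu(sweep(h1 %*% par$W2, 2, par$b2, `+`))
  mu <- sweep(h2 %*% par$Wmu, 2, par$bmu, `+`)
  lv <- sweep(h2 %*% par$Wlv, 2, par$blv, `+`)
  z <- if (is.null(eps)) mu else mu + exp(0.5 * lv) * eps
  d1 <- relu(sweep(cbind(z, yh) %*% par$V1, 2, par$c1, `+`))
  d2 <- relu(sweep(d1 %*% par$V2, 2, par$c2, `+`))
  t3 <- sweep(d2 %*% par$V3, 2, par$c3, `+`)
  xhat <- sigmoid(t3)
  logits <- sweep(mu %*% par$Wc, 2, par$bc, `+`)
  list(h1 = h1, h2 = h2, mu = mu, lv = lv, z = z, eps = eps,
       d1 = d1, d2 = d2, xhat = xhat, logits = logits)
}

cvae_loss_parts <- function(fw, x, yh, weights, recon_loss = "bce") {
  xh <- pmin(pmax(fw$xhat, 1e-7), 1 - 1e-7)
  recon <- if (recon_loss == "bce") {
    -mean(x * log(xh) + (1 - x) * log(1 - xh))
  } else mean((x - fw$xhat)^2)
  kl <- mean(0.5 * (fw$mu^2 + exp(fw$lv) - 1 - fw$lv))
  lmax <- pmax(fw$logits[, 1], fw$logits[, 2])
  lse <- lmax + log(exp(fw$logits[, 1] - lmax) + exp(fw$logits[, 2] - lmax))
  class <- mean(lse - rowSums(fw$logits * yh))
  total <- weights["recon"] * recon + weights["kl"] * kl + weights["class"] * class
  c(total = unname(total), recon = recon, kl = kl, class = class)
}

#' Evaluate the three-term loss on a batch
#'
#' Reconstruction is mean binary cross-entropy per matrix element (or MSE),
#' the KL term is the standard-normal KL of the latent posterior averaged
#' over batch and latent dimensions (so a posterior with mean `mu` and unit
#' variance contributes `mu^2/2` per dimension), and the classification term
#' is mean cross-entropy of the classifier logits. The total is the weighted
#' sum.
#'
#' @param model a trained `cvae_model` (or a bare parameter list plus
#'   `recon_loss`).
#' @param batch unit-scaled samples x genes matrix.
#' @param labels binary vector for the batch.
#' @param weights positive weights `c(recon, kl, class)`.
#' @param sample draw reparameterized latents (`TRUE`) or use the posterior
#'   mean (default, deterministic).
#' @param seed seed for the reparameterization draw when `sample = TRUE`.
#' @return Named numeric vector `c(total, recon, kl, class)`.
#' @export
cvae_loss <- function(model, batch, labels,
                      weights = c(recon = 1, kl = 1, class = 1),
                      sample = FALSE, seed = 1L) {
  par <- if (!is.null(model$params)) model$params else model
  rl <- if (!is.null(model$config$recon_loss)) model$config$recon_loss else "bce"
  yh <- encode_labels(labels)
  eps <- if (sample)
    with_seed(seed, matrix(rnorm(nrow(batch) * ncol(par$Wmu)),
                           nrow(batch), ncol(par$Wmu)))
  else NULL
  fw <- cvae_forward(par, batch, yh, eps)
  names(weights) <- c("recon", "kl", "class")
  out <- cvae_loss_parts(fw, batch, yh, weights, rl)
  if (any(!is.finite(out))) {
    bad <- names(out)[!is.finite(out)][1]
    stopf("non-finite loss term: %s", bad)
  }
  out
}

# hand-derived backward pass; returns gradients with the same shapes as par
cvae_backward <- function(par, fw, x, yh, weights, recon_loss = "bce") {
  n <- nrow(x); G <- ncol(x); L <- ncol(fw$mu)
  dt3 <- if (recon_loss == "bce") {
    weights["recon"] * (fw$xhat - x) / (n * G)
  } else weights["recon"] * 2 * (fw$xhat - x) * fw$xhat * (1 - fw$xhat) / (n * G)
  gV3 <- crossprod(fw$d2, dt3); gc3 <- colSums(dt3)
  dd2 <- (dt3 %*% t(par$V3)) * (fw$d2 > 0)
  gV2 <- crossprod(fw$d1, dd2); gc2 <- colSums(dd2)
  dd1 <- (dd2 %*% t(par$V2)) * (fw$d1 > 0)
  zin <- cbind(fw$z, yh)
  gV1 <- crossprod(zin, dd1); gc1 <- colSums(dd1)
  dz <- (dd1 %*% t(par$V1))[, seq_len(L), drop = FALSE]

  p <- exp(fw$logits - apply(fw$logits, 1, max))
  p <- p / rowSums(p)
  dlogits <- weights["class"] * (p - yh) / n
  gWc <- crossprod(fw$mu, dlogits); gbc <- colSums(dlogits)

  dmu <- dz + weights["kl"] * fw$mu / (n * L) + dlogits %*% t(par$Wc)
  dlv <- weights["kl"] * 0.5 * (exp(fw$lv) - 1) / (n * L)
  if (!is.null(fw$eps))
    dlv <- dlv + dz * fw$eps * 0.5 * exp(0.5 * fw$lv)

  gWmu <- crossprod(fw$h2, dmu); gbmu <- colSums(dmu)
  gWlv <- crossprod(fw$h2, dlv); gblv <- colSums(dlv)
  dh2 <- (dmu %*% t(par$Wmu) + dlv %*% t(par$Wlv)) * (fw$h2 > 0)
  gW2 <- crossprod(fw$h1, dh2); gb2 <- colSums(dh2)
  dh1 <- (dh2 %*% t(par$W2)) * (fw$h1 > 0)
  gW1 <- crossprod(cbind(x, yh), dh1); gb1 <- colSums(dh1)
  lapply(list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
              Wmu = gWmu, bmu = gbmu, Wlv = gWlv, blv = gblv,
              V1 = gV1, c1 = gc1, V2 = gV2, c2 = gc2, V3 = gV3, c3 = gc3,
              Wc = gWc, bc = gbc), unname)
}

#' Train the conditional VAE
#'
#' Minibatch Adam with fixed seeded initialization, shuffling and
#' reparameterization streams, so identical seeds give identical models. The
#' per-epoch loss trace (batch-size-weighted means of the four terms) is
#' recorded; a non-finite loss aborts with the epoch index.
#'
#' @param expr [expression_set()] on the log-NTPM scale (at least 2 samples
#'   per class).
#' @param config a [cvae_config()].
#' @return Object of class `cvae_model`: `params`, `config`, `bounds` (unit
#'   scaling), `gene_ids`, `trace` (data.frame epoch/total/recon/kl/class).
#' @export
cvae_train <- function(expr, config = cvae_config()) {
  stopifnot(inherits(expr, "expression_set"), inherits(config, "cvae_config"))
  if (min(table(expr$labels)) < 2) stopf("need at least 2 samples per class")
  sc <- scale_to_unit(expr)
  x_all <- sc$values
  yh_all <- expr$label_onehot
  n <- nrow(x_all); G <- ncol(x_all); L <- config$latent_dim
  bs <- min(config$batch_size, n)
  w <- config$loss_weights
  lr <- config$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  trace <- matrix(NA_real_, config$epochs, 4,
                  dimnames = list(NULL, c("total", "recon", "kl", "class")))
  with_seed(config$seed, {
    par <- cvae_init(G, config)
    m_st <- lapply(par, function(p) p * 0)
    v_st <- lapply(par, function(p) p * 0)
    t_step <- 0
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = bs)
      ep_loss <- c(total = 0, recon = 0, kl = 0, class = 0)
      for (st in starts) {
        idx <- perm[st:min(st + bs - 1, n)]
        x <- x_all[idx, , drop = FALSE]
        yh <- yh_all[idx, , drop = FALSE]
        eps <- matrix(rnorm(length(idx) * L), length(idx), L)
        fw <- cvae_forward(par, x, yh, eps)
        parts <- cvae_loss_parts(fw, x, yh, w, config$recon_loss)
        if (any(!is.finite(parts)))
          stopf("training diverged at epoch %d (non-finite %s loss)",
                epoch, names(parts)[!is.finite(parts)][1])
        ep_loss <- ep_loss + parts * length(idx)
        gr <- cvae_backward(par, fw, x, yh, w, config$recon_loss)
        t_step <- t_step + 1
        corr <- sqrt(1 - b2^t_step) / (1 - b1^t_step)
        for (nm in names(par)) {
          m_st[[nm]] <- b1 * m_st[[nm]] + (1 - b1) * gr[[nm]]
          v_st[[nm]] <- b2 * v_st[[nm]] + (1 - b2) * gr[[nm]]^2
          par[[nm]] <- par[[nm]] - lr * corr * m_st[[nm]] /
            (sqrt(v_st[[nm]]) + eps_adam)
        }
      }
      trace[epoch, ] <- ep_loss / n
    }
    structure(list(params = par, config = config, bounds = sc$bounds,
                   gene_ids = expr$gene_ids,
                   trace = data.frame(epoch = seq_len(config$epochs), trace)),
              class = "cvae_model")
  })
}

#' Encode expression profiles into the latent space
#'
#' Returns latent posterior means (not samples).
#'
#' @param model a `cvae_model`.
#' @param expr [expression_set()] or samples x genes matrix on the original
#'   scale (scaled internally with the model's training bounds).
#' @param labels binary vector (taken from `expr` when omitted).
#' @return Object of class `latent_embedding`: `coordinates` (samples x
#'   latent_dim), `labels`.
#' @export
cvae_encode <- function(model, expr, labels = NULL) {
  stopifnot(inherits(model, "cvae_model"))
  m <- if (inherits(expr, "expression_set")) expr$values else as.matrix(expr)
  if (is.null(labels) && inherits(expr, "expression_set")) labels <- expr$labels
  if (ncol(m) != length(model$bounds$min))
    stopf("gene count mismatch: model has %d genes, input has %d",
          length(model$bounds$min), ncol(m))
  rng <- ifelse(model$bounds$constant, 1, model$bounds$max - model$bounds$min)
  x <- sweep(sweep(m, 2, model$bounds$min), 2, rng, `/`)
  x[, model$bounds$constant] <- 0.5
  fw <- cvae_forward(model$params, x, encode_labels(labels), eps = NULL)
  structure(list(coordinates = fw$mu, labels = as.integer(labels)),
            class = "latent_embedding")
}

#' Decode latent points to the expression scale
#'
#' @param model a `cvae_model`.
#' @param z latent matrix (rows = points).
#' @param labels binary class label per point (conditions the decoder).
#' @return samples x genes matrix on the original log-NTPM scale.
#' @export
cvae_decode <- function(model, z, labels) {
  par <- model$params
  yh <- encode_labels(labels)
  d1 <- relu(sweep(cbind(z, yh) %*% par$V1, 2, par$c1, `+`))
  d2 <- relu(sweep(d1 %*% par$V2, 2, par$c2, `+`))
  xhat <- sigmoid(sweep(d2 %*% par$V3, 2, par$c3, `+`))
  inverse_scale(xhat, model$bounds)
}

#' Generate balanced expression profiles by latent KDE sampling
#'
#' Fits one product-Gaussian-kernel density per class on the embedded latent
#' coordinates (shared bandwidth, raw coordinates), draws `n_per_class`
#' latent points per class, decodes each with its class label, and returns
#' profiles on the original log-NTPM scale with balanced labels.
#'
#' @param model a `cvae_model`.
#' @param embedding a `latent_embedding` containing both classes (>= 2 points
#'   each).
#' @param n_per_class generated profiles per class.
#' @param bandwidth kernel bandwidth (default 0.2).
#' @param seed integer seed.
#' @return An [expression_set()] with `n_per_class` baseline rows followed by
#'   `n_per_class` variant rows.
#' @export
sample_profiles <- function(model, embedding, n_per_class, bandwidth = 0.2,
                            seed = 1L) {
  stopifnot(inherits(model, "cvae_model"), inherits(embedding, "latent_embedding"))
  z <- sample_latent(embedding, n_per_class, bandwidth, seed)
  vals <- rbind(cvae_decode(model, z$baseline, rep(0L, n_per_class)),
                cvae_decode(model, z$variant, rep(1L, n_per_class)))
  expression_set(vals, c(rep(0L, n_per_class), rep(1L, n_per_class)),
                 gene_ids = model$gene_ids)
}

#' Draw latent points from the per-class kernel density estimates
#'
#' One product-Gaussian-kernel KDE per class on the embedded coordinates:
#' a draw is a uniformly chosen embedded point of that class plus
#' `bandwidth * N(0, I)` kernel noise.
#'
#' @param embedding a `latent_embedding` with >= 2 points per class.
#' @param n_per_class draws per class.
#' @param bandwidth kernel bandwidth (default 0.2).
#' @param seed integer seed.
#' @return List with matrices `baseline` and `variant`
#'   (`n_per_class` x latent_dim each).
#' @export
sample_latent <- function(embedding, n_per_class, bandwidth = 0.2, seed = 1L) {
  stopifnot(inherits(embedding, "latent_embedding"))
  with_seed(seed, {
    out <- list()
    for (cls in c(0L, 1L)) {
      pts <- embedding$coordinates[embedding$labels == cls, , drop = FALSE]
      if (nrow(pts) < 2)
        stopf("class %d has fewer than 2 embedded points", cls)
      idx <- sample.int(nrow(pts), n_per_class, replace = TRUE)
      out[[cls + 1L]] <- pts[idx, , drop = FALSE] +
        bandwidth * matrix(rnorm(n_per_class * ncol(pts)), n_per_class)
    }
    list(baseline = out[[1]], variant = out[[2]])
  })
}

#' Per-gene two-sample t-test p-values
#'
#' Vectorized Welch t-tests of variant vs baseline for every gene; genes with
#' zero variance in both classes get p = 1.
#'
#' @param expr an [expression_set()] with >= 2 samples per class.
#' @return Numeric vector of p-values, one per gene.
#' @export
gene_pvalues <- function(expr) {
  y <- expr$labels
  if (min(table(y)) < 2) stopf("need at least 2 samples per class")
  m0 <- expr$values[y == 0, , drop = FALSE]
  m1 <- expr$values[y == 1, , drop = FALSE]
  n0 <- nrow(m0); n1 <- nrow(m1)
  v0 <- col_vars(m0); v1 <- col_vars(m1)
  se2 <- v0 / n0 + v1 / n1
  tt <- (colMeans(m1) - colMeans(m0)) / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[!is.finite(p)] <- 1
  p
}

#' Differential-expression retention AUROC
#'
#' Compares the genes called differentially expressed in the original data
#' with those called in the generated/reconstructed data: both gene lists are
#' ranked by t-test p-value, a common significance rank k is swept from 0 to
#' the gene count, and at each k the true-positive rate (fraction of the
#' original's top-k recovered in the reconstruction's top-k) is traded
#' against the false-positive rate (fraction of non-significant original
#' genes selected by the reconstruction). The area under the resulting curve
#' is returned (trapezoidal rule over FPR-sorted points).
#'
#' @param original,reconstructed [expression_set()]s over the same gene set.
#' @return List with `auroc` and `curve` (data.frame `fpr`, `tpr`).
#' @export
auroc_retention <- function(original, reconstructed) {
  if (!identical(original$gene_ids, reconstructed$gene_ids))
    stopf("gene sets must match")
  retention_curve(gene_pvalues(original), gene_pvalues(reconstructed))
}

#' Retention curve from two p-value rankings
#'
#' The curve construction behind [auroc_retention()], exposed for rankings
#' obtained by other means: both vectors are ranked (ties broken by index), a
#' common significance rank k sweeps 0..n, and at each k
#' `TPR = |top_k(original) intersect top_k(recon)| / k` and
#' `FPR = |top_k(recon) minus top_k(original)| / (n - k)`.
#'
#' @param p_original,p_reconstructed p-value vectors over the same genes.
#' @return List with `auroc` (trapezoid over FPR-sorted points) and `curve`.
#' @export
retention_curve <- function(p_original, p_reconstructed) {
  n <- length(p_original)
  if (length(p_reconstructed) != n) stopf("p-value vectors must match in length")
  pos_o <- integer(n); pos_o[order(p_original, seq_len(n))] <- seq_len(n)
  pos_r <- integer(n); pos_r[order(p_reconstructed, seq_len(n))] <- seq_len(n)
  inter <- cumsum(tabulate(pmax(pos_o, pos_r), nbins = n))
  ks <- seq_len(n - 1)
  fpr <- (ks - inter[ks]) / (n - ks)
  tpr <- inter[ks] / ks
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auroc = auroc, curve = data.frame(fpr = fpr, tpr = tpr))
}

#' Save a model checkpoint
#'
#' Single-file JSON container (versioned schema) holding all parameter
#' tensors, the configuration, and the unit-scaling bounds.
#'
#' @param model a `cvae_model`.
#' @param path output file.
#' @export
save_cvae <- function(model, path) {
  payload <- list(schema = "cvae-checkpoint-v1",
                  config = unclass(model$config),
                  gene_ids = model$gene_ids,
                  bounds = model$bounds,
                  param_dims = lapply(model$params, function(p)
                    if (is.matrix(p)) dim(p) else length(p)),
                  params = lapply(model$params, as.numeric))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_cvae()]
#' @param path checkpoint file.
#' @return A `cvae_model` (without the training trace).
#' @export
load_cvae <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(pl$schema, "cvae-checkpoint-v1"))
    stopf("unrecognized checkpoint schema: %s", pl$schema)
  params <- lapply(names(pl$params), function(nm) {
    dm <- pl$param_dims[[nm]]
    v <- as.numeric(pl$params[[nm]])
    if (length(dm) == 2) matrix(v, dm[1], dm[2]) else v
  })
  names(params) <- names(pl$params)
  cfg <- pl$config
  cfg$loss_weights <- stats::setNames(as.numeric(cfg$loss_weights),
                                      c("recon", "kl", "class"))
  class(cfg) <- "cvae_config"
  bounds <- pl$bounds
  bounds$constant <- as.logical(bounds$constant)
  structure(list(params = params, config = cfg, bounds = bounds,
                 gene_ids = pl$gene_ids, trace = NULL),
            class = "cvae_model")
}
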