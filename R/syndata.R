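#' Synthetic-data configuration
#'
#' Stated-world defaults for the synthetic generator: Gaussian noise on the
#' log-NTPM scale (`noise_sd = 0.5`), planted class shift of `3 * noise_sd`
#' along each causal direction (recoverable but not trivial), within-class
#' latent factor sd of `2 * noise_sd`, and a perturbation library that is 10%
#' overexpressions / 90% knockdowns.
#'
#' @param n_genes number of genes.
#' @param n_baseline,n_variant samples per phenotype class.
#' @param latent_rank number of planted orthonormal factor directions.
#' @param class_shift displacement of the variant class mean along each of the
#'   `n_causal` planted causal directions (expression units); default
#'   `3 * noise_sd`.
#' @param noise_sd isotropic Gaussian noise sd on the log scale.
#' @param n_causal number of planted causal directions.
#' @param n_perturbations number of columns in the synthetic response library.
#' @param frac_overexpression fraction of library columns tagged
#'   overexpression (rest are knockdowns).
#' @param factor_sd within-class sd of latent factor scores.
#' @param seed integer seed; all generator randomness flows from it.
#' @return A validated list of class `syn_config`.
#' @export
syn_config <- function(n_genes = 500, n_baseline = 100, n_variant = 100,
                       latent_rank = 10, class_shift = NULL, noise_sd = 0.5,
                       n_causal = 3, n_perturbations = 40,
                       frac_overexpression = 0.1, factor_sd = NULL, seed = 1L) {
  if (is.null(class_shift)) class_shift <- 3 * noise_sd
  if (is.null(factor_sd)) factor_sd <- 2 * noise_sd
  cfg <- list(n_genes = n_genes, n_baseline = n_baseline, n_variant = n_variant,
              latent_rank = latent_rank, class_shift = class_shift,
              noise_sd = noise_sd, n_causal = n_causal,
              n_perturbations = n_perturbations,
              frac_overexpression = frac_overexpression,
              factor_sd = factor_sd, seed = as.integer(seed))
  counts <- c("n_genes", "n_baseline", "n_variant", "latent_rank", "n_causal",
              "n_perturbations")
  for (f in counts) {
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stopf("%s must be a positive integer", f)
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  if (cfg$noise_sd <= 0) stopf("noise_sd must be > 0")
  if (cfg$frac_overexpression < 0 || cfg$frac_overexpression > 1)
    stopf("frac_overexpression must be in [0,1]")
  if (cfg$n_causal > cfg$latent_rank)
    stopf("n_causal must be <= latent_rank")
  if (cfg$latent_rank > min(cfg$n_genes, cfg$n_baseline + cfg$n_variant))
    stopf("latent_rank must be <= min(n_genes, n_samples)")
  structure(cfg, class = "syn_config")
}

#' Generate a two-cluster low-rank expression matrix with planted causal
#' directions
#'
#' Samples are drawn as `base_mean + Z Q^T + noise`, where `Q` holds
#' `latent_rank` orthonormal gene-space directions and the variant class mean
#' is displaced by `class_shift` along exactly `n_causal` of them. Values live
#' on the log-NTPM scale (baseline gene means Uniform(6, 12)).
#'
#' @param config a [syn_config()].
#' @return List with `expr` (an [expression_set()], baseline samples first)
#'   and `truth` (class `syn_truth`): `causal_indices` (indices into the
#'   planted directions), `causal_dirs` (genes x n_causal), `class_mean_delta`
#'   (gene-space displacement of the variant mean), `directions` (full Q),
#'   `base_mean`.
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  with_seed(config$seed, {
    G <- config$n_genes; L <- config$latent_rank
    n0 <- config$n_baseline; n1 <- config$n_variant; n <- n0 + n1
    Q <- qr.Q(qr(matrix(rnorm(G * L), G, L)))
    base_mean <- runif(G, 6, 12)
    labels <- c(rep(0L, n0), rep(1L, n1))
    Z <- matrix(rnorm(n * L, sd = config$factor_sd), n, L)
    shift <- rep(0, L); shift[seq_len(config$n_causal)] <- config$class_shift
    Z[labels == 1, ] <- sweep(Z[labels == 1, , drop = FALSE], 2, shift, `+`)
    Y <- rep(1, n) %o% base_mean + Z %*% t(Q) +
      matrix(rnorm(n * G, sd = config$noise_sd), n, G)
    delta <- as.numeric(Q[, seq_len(config$n_causal), drop = FALSE] %*%
                          rep(config$class_shift, config$n_causal))
    truth <- structure(list(causal_indices = seq_len(config$n_causal),
                            causal_dirs = Q[, seq_len(config$n_causal), drop = FALSE],
                            class_mean_delta = delta,
                            directions = Q, base_mean = base_mean,
                            config = config),
                       class = "syn_truth")
    list(expr = expression_set(Y, labels), truth = truth)
  })
}

#' Map planted causal directions to eigengene indices
#'
#' Planted directions are orthonormal and coincide with eigengenes of the
#' generated matrix up to noise; each is matched to the basis column with the
#' largest absolute inner product.
#'
#' @param truth a `syn_truth` from [generate_expression()].
#' @param basis an [eigengene_basis] from [compute_basis()].
#' @return Integer vector of basis column indices, one per causal direction.
#' @export
match_causal_eigengenes <- function(truth, basis) {
  ali <- abs(t(truth$causal_dirs) %*% basis$U)   # n_causal x l
  out <- integer(nrow(ali))
  # greedy unique assignment, strongest alignments first (a symmetric class
  # shift can rotate several planted directions onto one eigengene otherwise)
  for (step in seq_len(nrow(ali))) {
    pos <- which(ali == max(ali), arr.ind = TRUE)[1, ]
    out[pos[1]] <- pos[2]
    ali[pos[1], ] <- -Inf
    ali[, pos[2]] <- -Inf
  }
  out
}

#' Generate a synthetic perturbation-response library
#'
#' Produces one average gene-space response profile per perturbation. A
#' designated subset of `n_causal + 2` columns is constructed so that the sum
#' of its columns equals the planted class-mean displacement exactly, so the
#' indicator vector on that subset (`planted_u`) is a feasible steering
#' solution. Columns are tagged with gene symbols and a knockdown (KD) /
#' overexpression (OE) sign by `frac_overexpression`.
#'
#' @param config a [syn_config()].
#' @param basis an [eigengene_basis] computed from the generated data.
#' @param truth the matching `syn_truth`.
#' @param selected basis column indices onto which responses are projected;
#'   defaults to the eigengenes matched to the planted causal directions.
#' @param response_sd per-gene sd of the random response component.
#' @return A `perturbation_library` (see [build_library()]) with extra fields
#'   `response_profiles` (genes x P), `planted_u`, `planted_subset`.
#' @export
generate_perturbation_library <- function(config, basis, truth,
                                          selected = NULL, response_sd = 0.3) {
  stopifnot(inherits(config, "syn_config"), inherits(truth, "syn_truth"))
  if (nrow(basis$U) != length(truth$class_mean_delta))
    stopf("basis and truth disagree on gene dimension")
  if (is.null(selected)) selected <- match_causal_eigengenes(truth, basis)
  with_seed(derive_seed(config$seed, 101L), {
    G <- config$n_genes; P <- config$n_perturbations
    k <- min(P, config$n_causal + 2L)
    subset <- seq_len(k)
    W <- matrix(rnorm(G * P, sd = response_sd), G, P)
    # make designated columns sum exactly to the planted displacement
    Wk <- W[, subset, drop = FALSE]
    W[, subset] <- Wk - rowMeans(Wk) + truth$class_mean_delta / k
    planted_u <- as.numeric(seq_len(P) %in% subset)
    n_oe <- round(config$frac_overexpression * P)
    sign <- sample(c(rep("OE", n_oe), rep("KD", P - n_oe)))
    meta <- data.frame(column = sprintf("pert%03d", seq_len(P)),
                       gene = sprintf("GENE%04d", sample.int(9999L, P)),
                       sign = sign, stringsAsFactors = FALSE)
    lib <- build_library(W, basis, selected, meta)
    lib$response_profiles <- W
    lib$planted_u <- planted_u
    lib$planted_subset <- subset
    lib
  })
}

#' Generate a transition instance set with planted feasible solutions
#'
#' Builds baseline and variant state clusters directly in causal-eigengene
#' coordinates, together with a response matrix `B`, such that every
#' baseline-variant difference lies in the feasible set
#' `{B u : u in [0,1]^P}`: states are `base + B a` with small non-negative
#' coefficient vectors `a`, and the cluster displacement is `B u_delta` with
#' `u_delta` in [0.3, 0.6] on a sparse support, so pairwise differences have
#' exact box-feasible solutions.
#'
#' @param r number of causal-eigengene coordinates.
#' @param P number of perturbations (columns of `B`).
#' @param n_baseline,n_variant states per cluster.
#' @param k_active size of the support of the planted displacement weights.
#' @param within_scale upper bound of the per-state coefficient draws.
#' @param seed integer seed.
#' @return List with `baseline_states`, `variant_states` (rows = states),
#'   `B` (r x P), `u_delta`, and `meta` (gene/sign tags as in the library).
#' @export
generate_transition_set <- function(r = 20, P = 60, n_baseline = 30,
                                    n_variant = 30, k_active = 8,
                                    within_scale = 0.15, seed = 1L) {
  stopifnot(k_active <= P, within_scale < 0.3)
  with_seed(seed, {
    B <- matrix(rnorm(r * P), r, P)
    support <- sample.int(P, k_active)
    u_delta <- rep(0, P)
    u_delta[support] <- runif(k_active, 0.3, 0.6)
    base <- rnorm(r, sd = 2)
    # within-cluster variation lives on the support of u_delta, so the
    # planted pair solution u_delta + a_variant - a_baseline stays in
    # [0.3 - within_scale, 0.6 + within_scale] there and 0 elsewhere
    A0 <- matrix(0, n_baseline, P)
    A0[, support] <- runif(n_baseline * k_active, 0, within_scale)
    A1 <- matrix(0, n_variant, P)
    A1[, support] <- runif(n_variant * k_active, 0, within_scale)
    baseline_states <- rep(1, n_baseline) %o% base + A0 %*% t(B)
    variant_states <- rep(1, n_variant) %o% (base + as.numeric(B %*% u_delta)) +
      A1 %*% t(B)
    n_oe <- round(0.1 * P)
    sign <- sample(c(rep("OE", n_oe), rep("KD", P - n_oe)))
    meta <- data.frame(column = sprintf("pert%03d", seq_len(P)),
                       gene = sprintf("GENE%04d", sample.int(9999L, P)),
                       sign = sign, stringsAsFactors = FALSE)
    # planted u for the forward pair (i, j) is
    # u_delta + coef_variant[i, ] - coef_baseline[j, ], always inside [0,1]
    list(baseline_states = baseline_states, variant_states = variant_states,
         B = B, u_delta = u_delta, coef_baseline = A0, coef_variant = A1,
         meta = meta)
  })
}

#' Generate a binary bipartite matrix with planted co-occurring column pairs
#'
#' Entries are independent Bernoulli(`density`) except for planted column
#' pairs: per row, with probability `boost` both entries of the pair are
#' forced to 1, raising their joint occurrence probability to
#' `boost + (1 - boost) * density^2`.
#'
#' @param n_rows,n_cols matrix dimensions.
#' @param density baseline Bernoulli rate, in (0,1).
#' @param planted_pairs list of length-2 integer vectors (column indices).
#' @param boost joint-occurrence boost, in (0,1); `density + boost <= 1`.
#' @param seed integer seed.
#' @return Binary `n_rows x n_cols` matrix.
#' @export
generate_bipartite <- function(n_rows, n_cols, density,
                               planted_pairs = list(), boost = 0, seed = 1L) {
  if (density <= 0 || density > 1) stopf("density must be in (0,1]")
  if (boost < 0 || boost >= 1) stopf("boost must be in [0,1)")
  if (density < 1 && density + boost > 1) stopf("density + boost must be <= 1")
  for (pr in planted_pairs)
    if (length(pr) != 2 || any(pr < 1) || any(pr > n_cols))
      stopf("planted pair indices out of range")
  with_seed(seed, {
    A <- matrix(rbinom(n_rows * n_cols, 1, density), n_rows, n_cols)
    for (pr in planted_pairs) {
      on <- rbinom(n_rows, 1, boost) == 1
      A[on, pr[1]] <- 1L
      A[on, pr[2]] <- 1L
    }
    A
  })
}

#' Generate negative-binomial counts with companion lengths and labels
#'
#' Count-level generator used to exercise the curation module (the continuous
#' pipeline itself consumes log-NTPM matrices). Gene means are log-normal,
#' dispersion is shared, and a handful of genes/samples are made to fail the
#' curation filters on purpose.
#'
#' @param n_genes,n_samples dimensions.
#' @param mean_log,sd_log log-normal parameters of gene mean counts (defaults
#'   give library sizes comfortably above the 1e5 sample filter from about
#'   100 genes up).
#' @param size negative-binomial size (inverse dispersion).
#' @param seed integer seed.
#' @return List with `counts` (a [counts_table()]) and `lengths` (named
#'   vector of transcript lengths).
#' @export
generate_counts <- function(n_genes = 200, n_samples = 30, mean_log = 6,
                            sd_log = 1.5, size = 5, seed = 1L) {
  with_seed(seed, {
    mu <- exp(rnorm(n_genes, mean_log, sd_log))
    # plant a few clearly low-abundance genes
    mu[seq_len(max(1, n_genes %/% 20))] <- runif(max(1, n_genes %/% 20), 0.1, 2)
    v <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu, size = size),
                n_genes, n_samples)
    labels <- rbinom(n_samples, 1, 0.5)
    gene_ids <- sprintf("G%05d", seq_len(n_genes))
    lengths <- stats::setNames(round(runif(n_genes, 500, 5000)), gene_ids)
    list(counts = counts_table(v, gene_ids, sprintf("S%03d", seq_len(n_samples)),
                               labels),
         lengths = lengths)
  })
}

#' Write a full synthetic dataset in the formats the curation CLI reads
#'
#' Emits a gene x sample counts TSV, a two-column gene-length TSV, and a
#' one-column label file, so synthetic data can exercise the whole CLI path.
#'
#' @param dir output directory (created if needed).
#' @param n_genes,n_samples,seed forwarded to [generate_counts()].
#' @return Invisibly, named vector of the three file paths.
#' @export
write_synthetic_dataset <- function(dir, n_genes = 200, n_samples = 30,
                                    seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- generate_counts(n_genes = n_genes, n_samples = n_samples, seed = seed)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             lengths = file.path(dir, "gene_lengths.tsv"),
             labels = file.path(dir, "labels.tsv"))
  write_counts_tsv(g$counts, paths["counts"], paths["labels"])
  data.table::fwrite(data.frame(gene = names(g$lengths),
                                length = as.numeric(g$lengths)),
                     paths["lengths"], sep = "\t")
  invisible(paths)
}
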