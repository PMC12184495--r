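# eigensteer

Complex traits — inflammatory bowel disease, allergic asthma, cancer
metastasis — rarely trace back to a single gene. Transcriptomic case/control
studies measure tens of thousands of genes on a few dozen samples, so
per-gene differential-expression tests are underpowered and say nothing
about which *combinations* of genes could move a cell between phenotypes.
`eigensteer` implements a generative pipeline that turns phenotype-labeled
expression matrices into candidate causal gene *sets*:

1. **Generative model.** A label-conditioned variational autoencoder
   (encoder → latent space Z, decoder, and a linear latent classifier) is
   trained on log-NTPM expression profiles with a three-term loss
   (reconstruction + KL regularization + classification). Per-class kernel
   density estimates over Z (Gaussian product kernel, bandwidth 0.2) are
   sampled and decoded into a balanced, denoised cohort Y.
2. **Eigengenes.** The SVD `Y' = U Σ V'` gives an orthonormal gene-space
   basis (eigengenes, columns of U); the data are projected onto the d = 200
   eigengenes with the largest singular values, `X = Y U[, 1:d]`.
3. **Bayesian fine-mapping.** A ridge logistic regression of the phenotype
   on X yields per-sample log-odds ζ; with the summary z-value `ξ = X'ζ/d`
   and correlation matrix `R = X'X/(dσ²)`, a Metropolis chain over binary
   causal vectors γ (likelihood `N(ξ | 0, R + R·ds²diag(γ)·R)`, prior
   `(1/d)^k (1−1/d)^(d−k)`) produces posterior inclusion probabilities; the
   top-r eigengenes are the causal subspace.
4. **Steering.** Given a library B of average transcriptional responses to
   single-gene knockdowns/overexpressions (expressed in causal-eigengene
   coordinates), the bounded L1-penalized problem
   `u* = argmin_{0≤u≤1} ‖x_to − x_from − Bu‖ + λΣu` finds sparse
   perturbation combinations steering one state onto another, scored by
   `R² = 1 − D(u*)/D(0)`. A λ-sweep keeps the sparsest solution with
   R² > 0.99, repeated over thousands of random baseline–variant pairs in
   both directions.
5. **Co-occurrence network.** Accepted (binarized) solutions stack into a
   bipartite matrix A; observed pair frequencies `f = A'A/N` are compared to
   a maximum-entropy null with the same expected row/column sums
   (`p_ij = 1/(1+e^{−(β_i+γ_j)})`, multipliers fitted by damped fixed-point
   iteration), giving z-scores and a thresholded network of perturbations
   that co-occur far more often than chance.

Every stage has a seeded synthetic generator (`syn_config()`,
`generate_expression()`, `generate_perturbation_library()`,
`generate_transition_set()`, `generate_bipartite()`, `generate_counts()`),
so the full pipeline is testable offline, and a `curate` path reproduces
GEO-style count curation (samples with > 1e5 total counts, genes with mean
count > 5, NTPM normalization, `log10(NTPM + 1e-10) + 10`).

## Worked example

```r
library(eigensteer)

# synthetic trait cohort: 500 genes, 100 baseline + 100 variant samples,
# one planted causal direction
cfg <- syn_config(n_genes = 500, n_baseline = 100, n_variant = 100,
                  latent_rank = 10, n_causal = 1, class_shift = 5, seed = 7)
g <- generate_expression(cfg)

# generative model -> balanced denoised cohort
model <- cvae_train(g$expr, cvae_config(epochs = 500, batch_size = 50, seed = 1))
emb   <- cvae_encode(model, g$expr)
gen   <- sample_profiles(model, emb, n_per_class = 100, seed = 2)
auroc_retention(g$expr, gen)$auroc

# eigengenes + fine-mapping on the generated matrix
basis <- compute_basis(gen)
proj  <- project_eigengenes(gen, basis, d = 200)
res   <- finemap_eigengenes(proj, gen$labels,
                            finemap_hyper(n_steps = 1e5, burn_in = 1e3,
                                          seed = 1, r = 10))

# steering between cluster centroids in causal-eigengene coordinates
lib <- generate_perturbation_library(cfg, basis, g$truth, selected = res$selected)
Xb  <- gen$values[gen$labels == 0, ] %*% basis$U[, res$selected]
Xv  <- gen$values[gen$labels == 1, ] %*% basis$U[, res$selected]
sol <- steer_centroids(Xb, Xv, lib)

# pairwise sweep + co-occurrence statistics
sw <- sweep_pairs(Xb, Xv, lib, n_pairs = 150, directions = "forward", seed = 3)
st <- cooccurrence_stats(sw$A)
```

Output of this exact script (printed by the session it was developed in):

```
AUROC retention: 0.896
variance remaining after d=200: 0.0000
logistic fit accuracy: 1.000 | top PIPs: 1.00, 0.02, 0.02, 0.02
selected eigengenes: 2 105 38 193 184
centroid steering: R^2 = 1.0000 at lambda = 0.215; top perturbations: GENE2677+, GENE9270-, GENE6697-
accepted 150 / 150 pairs; median perturbations per solution: 10
max co-occurrence z: 10.0
network at z > 20: 0 nodes, 0 edges
```

Reading: the generated cohort retains ~90% of the differential-expression
ranking (AUROC 0.896); one eigengene (index 2) carries the planted causal
signal (PIP 1.00, all others ≤ 0.02); the centroid transition is closed
exactly (R² = 1) by a sparse perturbation set even at a fairly large L1
weight; every sampled pair is steerable with R² > 0.99 using a median of 10
perturbations. No column pairs were planted to co-occur, so the z-matrix
tops out at 10 and the network at the strict z > 20 threshold is — correctly
— empty (`qq_points()` exists to re-choose the threshold by inspection when
the tail does deviate).

## Command line

```sh
Rscript -e 'eigensteer::eigensteer_cli()' curate --counts counts.tsv \
    --lengths gene_lengths.tsv --labels labels.tsv --out-prefix curated
Rscript -e 'eigensteer::eigensteer_cli()' train --expr-prefix curated --config config.yaml
Rscript -e 'eigensteer::eigensteer_cli()' generate --checkpoint model.json --expr-prefix curated
Rscript -e 'eigensteer::eigensteer_cli()' eigengenes --expr-prefix generated --d 200
Rscript -e 'eigensteer::eigensteer_cli()' finemap --projected basis_projected.tsv --labels labels.tsv
Rscript -e 'eigensteer::eigensteer_cli()' optimize --baseline b.tsv --variant v.tsv \
    --responses B.tsv --meta meta.tsv
Rscript -e 'eigensteer::eigensteer_cli()' cooccur --occurrence sweep_A.tsv --z-threshold 20
```

## Vignette

`vignettes/steering-complex-traits.Rmd` documents the model assumptions,
every tunable parameter with its default and rationale, what the synthetic
generators do and do not emulate, numerical choices (jitter, clamps,
tie-breaks, solver refinement), and known limitations.
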