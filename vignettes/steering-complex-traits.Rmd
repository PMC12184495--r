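---
title: "Steering complex-trait transcriptomes: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steering complex-trait transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

A complex trait presents as two transcriptional phenotypes — a *baseline*
and a *variant* cluster of expression profiles — with many genes, few
samples, and heterogeneity inside each cluster. `eigensteer` treats the
question "which genes cause the difference?" as a control problem: find
sparse combinations of experimentally measured single-gene perturbation
responses that move one state onto the other in a reduced coordinate system
learned from the data.

The pipeline has five stages, each usable on its own:

1. **Conditional VAE** (`cvae_train`, `sample_profiles`). Encoder
   `[profile, one-hot label] → 256 → 128 → (μ, log σ²)`, decoder
   `[z, one-hot label] → 128 → 256 → sigmoid`, and a single linear
   classifier on μ. The loss is a weighted sum of per-element binary
   cross-entropy (on per-gene min-max-scaled data, matching the sigmoid
   head), the standard-normal KL of the posterior, and classifier
   cross-entropy. Sampling fits one Gaussian-kernel KDE per class on the
   latent posterior means and decodes fresh draws, giving a balanced,
   denoised cohort.
2. **Eigengenes** (`compute_basis`, `project_eigengenes`). Thin SVD of the
   transposed generated matrix; eigengenes are the left singular vectors in
   gene space. Projection keeps the `d = 200` largest singular values.
3. **Fine-mapping** (`finemap_eigengenes`). Ridge logistic regression gives
   per-sample log-odds ζ; the summary statistics `ξ = X'ζ/d` and
   `R = X'X/(dσ²)` feed a Metropolis chain over binary causal indicator
   vectors γ with likelihood `N(ξ | 0, R + R·(ds²diag γ)·R)` and the
   rate-1/d binomial prior on the number of causal effects. Posterior
   inclusion probabilities are post-burn-in means of each γ_i.
4. **Steering** (`solve_transition`, `lambda_sweep`, `sweep_pairs`).
   `min_{u∈[0,1]^P} ‖x_to − x_from − Bu‖ + λΣu`, with B the
   perturbation-response library projected onto the selected causal
   eigengenes. Efficacy is `R² = 1 − D(u)/D(0)`; a pair is accepted at the
   largest λ on the grid with `R² > 0.99` (the sparsest acceptable
   solution).
5. **Co-occurrence network** (`cooccurrence_stats`, `build_cooc_graph`).
   Binarized accepted solutions form a binary matrix A; observed pair
   frequencies `A'A/N` are z-scored against a maximum-entropy bipartite
   null with the observed expected row/column sums.

## Assumptions

- Phenotype is well reflected by transcription; a linear readout of a
  learned latent space can classify it.
- Perturbation responses combine **additively** in eigengene coordinates,
  and the library is diverse enough to span trait-relevant directions.
- Euclidean distance in causal-eigengene space is a meaningful proxy for
  phenotypic proximity (each causal eigengene contributes equally).
- Accepted steering solutions are exchangeable rows for the null model: the
  maximum-entropy ensemble treats cells of A as independent Bernoulli
  variables given the margins.

# Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `hidden_sizes` | (256, 128) | encoder widths, mirrored by the decoder |
| `learning_rate` | 1e-4 | Adam |
| `epochs` | [500, 1e4], default 500 | warned outside the range, not refused |
| `batch_size` | [50, 200], default 50 | capped at the sample count |
| `loss_weights` | (1, 1, 1) | see "Loss scales" below |
| `latent_dim` | 16 | unspecified upstream; latent PCs are inspected, so > 2 |
| `kde_bandwidth` | 0.2 | raw (unstandardized) latent coordinates |
| `d` | 200 | eigengenes kept; errors (not truncates) if rank < d |
| `s` (initial) | 0.05 | scale hyperparameter of the causal prior |
| `n_steps`, `burn_in` | 1e5, 1e3 | Metropolis chain |
| `r` | 50 | causal-set size (10 suits a trait with few causal dimensions) |
| ridge | 1.0 | logistic penalty on unit-RMS-scaled columns |
| λ grid | 25 log-spaced in [1e-4, 10] | sweep grid |
| `r2_min` | 0.99 | strict acceptance bound |
| binarization threshold | 0.01 | occurrence indicator for A |
| z threshold | 20 | network edge cut; re-choose via `qq_points()` |
| null `tol` / damping | 1e-10 / 0.5 | fixed-point iteration on the multipliers |

## Loss scales

The KL term is averaged over batch **and** latent dimensions (a posterior
with mean μ and unit variance contributes μ²/2 per dimension) and the
reconstruction term is mean BCE per matrix element. On these scales the
three default unit weights are commensurate: with KL summed over 16 latent
dimensions instead, the regularizer would dominate the classifier by an
order of magnitude and collapse the label signal out of the latent space.

# The synthetic world

`generate_expression()` draws `base + Z Q' + ε`: orthonormal latent
directions Q (rank 10 by default), within-class factor scores with
sd `2 × noise_sd`, isotropic Gaussian noise (`noise_sd = 0.5`, log scale),
baseline gene means Uniform(6, 12) on the log-NTPM scale, and a variant
class mean displaced by `class_shift = 3 × noise_sd` along each of
`n_causal` planted directions. The displacement is three noise standard
deviations — recoverable but not trivial — and the factor scale sits below
it so planted directions surface as eigengenes without drowning the class
signal.

`generate_perturbation_library()` makes random per-gene responses
(sd 0.3) and rewrites a designated subset of `n_causal + 2` columns so they
sum *exactly* to the planted class displacement: the indicator vector on
that subset is a box-feasible steering solution by construction. The
composition defaults to 10% overexpressions / 90% knockdowns, matching the
real library it emulates.

`generate_transition_set()` builds clusters directly in eigengene
coordinates: states are `base + B a` with coefficients supported on the
support of the planted displacement weights `u_Δ ∈ [0.3, 0.6]` and bounded
by 0.15, so the planted solution of every forward pair,
`u_Δ + a_variant − a_baseline`, lies inside `[0.15, 0.75]` on the support
and at 0 elsewhere — exact feasibility for **every** pair, not just
centroids. Reverse transitions are *not* planted feasible (responses are
not antialigned), mirroring the asymmetry the bounded formulation is meant
to expose.

`generate_bipartite()` plants co-occurring column pairs by forcing both
entries to 1 with probability `boost`, giving joint rate
`boost + (1 − boost)·density²` against an independent-Bernoulli background.

What the generators do **not** emulate: library-size and gene-length biases
(counts are only exercised through the negative-binomial `generate_counts`
path for the curation module), batch effects, single-cell dropout,
correlated noise, non-additive perturbation interactions, or realistic
response-profile correlation structure. A green test therefore establishes
that the *algorithms* recover planted structure under their own modeling
assumptions — not that those assumptions hold on any particular GEO series.

# Numerical choices

**σ² in the fine-mapping likelihood.** The upstream description defines ζ
as the logit of the fitted class probabilities, which makes the naive
residual `ζ − Xβ` identically zero wherever the probability clamp
(`[1e-6, 1−1e-6]`) is inactive; a floored residual-variance estimator then
collapses the likelihood's signal-to-null contrast (a strongly planted
causal eigengene got PIP ≈ 0.01 in development). The default is instead the
self-consistent scale `σ² = √d`: under the null, `Cov(ξ) = σ_ε² X'X/d²`,
which equals the asserted `R = X'X/(dσ²)` exactly when `σ² = d/σ_ε²`;
requiring the plugged-in variance to equal the noise variance itself gives
the fixed point `σ² = √d`. With it, planted recovery is clean (PIP 1.0
causal vs ≈ 0.004 median elsewhere). `sigma2_method = "residual"` restores
the floored residual estimator.

**Likelihood evaluation.** Flipping one γ_i perturbs the covariance by a
symmetric rank-one term, so the chain evaluates the exact log-density via
the matrix determinant lemma and Woodbury identity on the active set
(O(k³) per step, k = number of causal effects). When `chol(R)` fails
(samples < d), a jitter `1e-8·tr(R)/d`, escalated tenfold up to 1e8×, is
added to R itself; the standalone `log_likelihood` and the chain share this
convention, so the exhaustive-enumeration oracle and the chain target agree
exactly.

**s updates.** The chain proposes `s' = s·exp(N(0, 0.1))` every 10th step
with the Jacobian-corrected ratio — a flat prior on s. (Nothing upstream
specifies the scheme; this is the package's choice.)

**Steering solver.** L-BFGS-B from the documented start `u = 0`
(`factr = 10`, `pgtol = 1e-12`). The objective — a norm of an affine map
plus a linear term — is convex, so the box-constrained solution is global;
a two-stage grid is therefore an exact 1e-3-resolution oracle in tests.
When an exact fit is attainable the optimum is the minimum-L1 vertex of
`{u ∈ box : Bu = Δ}`, which quasi-Newton iterations cannot reach along the
norm's kink (they stall on the feasible manifold with spurious small
weights); that case is refined exactly through the corresponding linear
program (solved as a strictly convex QP with a 1e-9 ridge) and the
refinement is kept only when the true objective improves. The refinement is
what makes binarized support sizes cleanly non-increasing along the λ path.

**Binarization.** The co-occurrence formalism treats entries of A as
occurrence indicators (a Bernoulli null is posited for them), so accepted
weight vectors are binarized at a strict 0.01 threshold before stacking.

**Bipartite convention for the null.** The printed fixed-point equations
carry unipartite-style `j ≠ i` exclusions, but rows (state pairs) and
columns (perturbations) of A index different entities; sums here run over
all opposite-side indices. Updates are damped 0.5 against oscillation;
convergence is max-norm change of p below 1e-10; all-ones/all-zeros rows
and columns are removed first and re-inserted with p pinned to 1/0
(their multipliers diverge).

**σ of the null frequencies.** "Error propagation" is implemented as the
variance of a mean of independent Bernoulli products,
`σ² = Σ_α p_αμ p_αν (1 − p_αμ p_αν)/N²`, consistent with the
maximum-entropy factorization; a Monte-Carlo oracle in the tests guards the
approximation (within 10% relative).

**Curation order.** The sample filter (total > 1e5, strict) runs before the
gene filter (mean > 5, strict, over surviving samples), so failed libraries
do not dilute gene means; one pass each. The order is a documented choice —
upstream lists both criteria jointly.

**Other conventions.** Eigengene signs are fixed by making the
largest-magnitude entry of each column positive (SVD signs are arbitrary;
downstream B matrices must be reproducible). No centering before the SVD
(`center = FALSE` default; eigengene 1 then tracks the mean profile and
doubles as the regression intercept, which the log-odds model lacks).
Selection ties break toward the lower index. Pair sampling is uniform with
replacement. All randomness flows from one seed per stage through a single
RNG gate that restores the caller's stream.

# Open-design decisions

- **Decoder conditioning:** the decoder receives the one-hot label
  alongside z (conditional decoder), mirroring the conditional encoder;
  only the encoder's conditioning is stated upstream. Decoding with an
  explicit label is what lets class-specific KDE draws produce labeled
  profiles.
- **KDE on posterior means,** not sampled codes: the means are the stable
  per-sample representation the classifier also uses; kernel noise already
  provides the stochasticity.
- **N pairs per direction:** `n_pairs` counts sampled pairs per direction
  (forward and reverse each see `n_pairs` attempts).
- **Early stopping:** none; fixed epoch count per configuration.

# Limitations

- CPU-bound, desk-scale training (pure-R BLAS); tens of thousands of genes
  at 1e4 epochs would need a compiled backend.
- In-sample metrics throughout (accuracy curves, fit metrics); no held-out
  evaluation, matching the upstream protocol.
- Only Euclidean distance in eigengene space; no non-additive response
  models; two phenotype classes only.
- The residual-variance σ² estimator is retained only for completeness; it
  is degenerate for confidently fitted models (see above).
- No credible sets or multi-chain convergence diagnostics beyond the
  step-doubling stability check in the tests.
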