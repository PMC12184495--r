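# Bayesian fine-mapping of causal eigengenes: a ridge-regularized logistic
# fit supplies per-sample log-odds zeta; the summary z-value xi = X' zeta / d
# and correlation matrix R = X'X / (d sigma^2) feed a multivariate-normal
# likelihood over binary causal vectors gamma, explored by Metropolis MCMC.

#' Ridge-regularized logistic regression over eigengenes
#'
#' Fits class labels on the projected matrix `X` (no intercept; the first,
#' uncentered eigengene plays that role). Columns are scaled to unit root
#' mean square internally so the ridge penalty acts on standardized
#' coefficients; fitted probabilities are clamped away from \{0, 1\} before
#' the logit so the per-sample log-odds stay finite.
#'
#' Two estimators of the log-odds noise variance `sigma2` are available.
#' `"calibrated"` (default) sets `sigma2 = sqrt(d)`: under the null the
#' sampling covariance of the summary z-value `xi = X' zeta / d` is
#' `sigma_eps^2 X'X / d^2`, which matches the asserted null covariance
#' `R = X'X / (d sigma2)` exactly when `sigma2 = d / sigma_eps^2`; demanding
#' that the variance plugged into `R` equal the noise variance itself gives
#' the fixed point `sigma2 = sqrt(d)`. `"residual"` uses the sample variance
#' of `zeta - X beta` (floored at `sigma2_min`), which is degenerate whenever
#' the probability clamp is inactive (the residual is then identically zero).
#'
#' @param X samples x d matrix or `projected_data`.
#' @param labels binary vector (0/1).
#' @param ridge ridge penalty on standardized coefficients (default 1).
#' @param clamp probability clamp bound (default 1e-6).
#' @param sigma2_method `"calibrated"` (default) or `"residual"`; see above.
#' @param sigma2_min floor for the residual-variance estimator (default 1e-2).
#' @return Object of class `regression_fit`: `beta`, `rho`, `zeta`, `sigma2`,
#'   `accuracy`, `f1`, `recall`.
#' @export
fit_logistic <- function(X, labels, ridge = 1, clamp = 1e-6,
                         sigma2_method = c("calibrated", "residual"),
                         sigma2_min = 1e-2) {
  sigma2_method <- match.arg(sigma2_method)
  if (inherits(X, "projected_data")) X <- X$X
  X <- as.matrix(X)
  y <- as.numeric(labels)
  if (!is_binary01(y)) stopf("labels must be binary")
  if (length(unique(y)) < 2) stopf("both classes must be present")
  scl <- sqrt(colMeans(X^2))
  scl[scl == 0] <- 1
  Xs <- sweep(X, 2, scl, `/`)
  d <- ncol(Xs)
  b <- rep(0, d)
  obj <- function(b) {
    eta <- as.numeric(Xs %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + 0.5 * ridge * sum(b^2)
  }
  f_cur <- obj(b)
  for (it in seq_len(100)) {
    eta <- as.numeric(Xs %*% b)
    p <- sigmoid(eta)
    g <- as.numeric(crossprod(Xs, p - y)) + ridge * b
    W <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xs * sqrt(W)) + diag(ridge, d)
    step <- tryCatch(solve(H, g), error = function(e)
      stopf("singular design in logistic fit: %s", conditionMessage(e)))
    alpha <- 1
    repeat {
      b_new <- b - alpha * step
      f_new <- obj(b_new)
      if (f_new <= f_cur + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    moved <- max(abs(b_new - b))
    b <- b_new; f_cur <- f_new
    if (moved < 1e-10) break
  }
  beta <- b / scl
  eta <- as.numeric(X %*% beta)
  rho <- pmin(pmax(sigmoid(eta), clamp), 1 - clamp)
  zeta <- logit(rho)
  sigma2 <- if (sigma2_method == "calibrated") sqrt(d)
            else max(stats::var(zeta - eta), sigma2_min)
  pred <- as.integer(rho > 0.5)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (isTRUE(prec + recall > 0)) 2 * prec * recall / (prec + recall) else 0
  structure(list(beta = beta, rho = rho, zeta = zeta, sigma2 = sigma2,
                 accuracy = mean(pred == y), f1 = f1, recall = recall),
            class = "regression_fit")
}

#' Summary z-value of the projected data
#'
#' `xi = X' zeta / d`.
#'
#' @param X samples x d matrix or `projected_data`.
#' @param zeta per-sample log-odds.
#' @param d divisor (defaults to `ncol(X)`).
#' @return Numeric d-vector.
#' @export
z_value <- function(X, zeta, d = NULL) {
  if (inherits(X, "projected_data")) X <- X$X
  if (is.null(d)) d <- ncol(X)
  as.numeric(crossprod(X, zeta)) / d
}

#' Eigengene correlation matrix
#'
#' `R = X'X / (d sigma2)`; symmetric positive semidefinite.
#'
#' @param X samples x d matrix or `projected_data`.
#' @param sigma2 residual variance from [fit_logistic()].
#' @param d divisor (defaults to `ncol(X)`).
#' @return d x d matrix.
#' @export
correlation_matrix <- function(X, sigma2, d = NULL) {
  if (inherits(X, "projected_data")) X <- X$X
  if (sigma2 <= 0) stopf("sigma2 must be > 0")
  if (is.null(d)) d <- ncol(X)
  R <- crossprod(X) / (d * sigma2)
  (R + t(R)) / 2
}

#' Log prior over causal configurations
#'
#' Uniform-rate prior on the number of causal effects:
#' `k log(1/d) + (d - k) log(1 - 1/d)` for `k = sum(gamma)`. Sums to 1 over
#' all `2^d` configurations by the binomial theorem.
#'
#' @param gamma binary d-vector (or an integer `k` with attribute-free use via
#'   `sum`).
#' @param d dimension.
#' @return Log prior mass (`-Inf` sentinel where the mass is zero).
#' @export
log_prior <- function(gamma, d) {
  if (d < 1) stopf("d must be >= 1")
  k <- sum(gamma)
  t1 <- if (k == 0) 0 else k * log(1 / d)
  t2 <- if (k == d) 0 else (d - k) * log1p(-1 / d)
  t1 + t2
}

# chol-based linear solve
chol_solve <- function(ch, b) backsolve(ch, forwardsolve(t(ch), b))

# Factor R once (with escalating jitter eps = 1e-8 * trace/d when chol
# fails) and precompute the pieces the Woodbury evaluation needs.
finemap_prep <- function(xi, R) {
  d <- length(xi)
  eps0 <- 1e-8 * sum(diag(R)) / d
  jitter <- 0
  ch <- NULL
  for (mult in c(0, 10^(0:8))) {
    jitter <- eps0 * mult
    ch <- tryCatch(chol(R + diag(jitter, d)), error = function(e) NULL)
    if (!is.null(ch)) break
  }
  if (is.null(ch)) stopf("covariance not factorizable even after max jitter")
  C0i_xi <- chol_solve(ch, xi)
  C0i_R <- chol_solve(ch, R)
  G <- R %*% C0i_R
  G <- (G + t(G)) / 2
  list(d = d, logdetC0 = 2 * sum(log(diag(ch))),
       a = sum(xi * C0i_xi), w = as.numeric(R %*% C0i_xi), G = G,
       jitter = jitter)
}

# log MVN(xi | 0, C0 + t R_S R_S') for active set S and t = d s^2, via the
# matrix determinant lemma and Woodbury identity (exact).
ll_active <- function(prep, S, t) {
  k <- length(S)
  if (k == 0)
    return(-0.5 * (prep$d * log(2 * pi) + prep$logdetC0 + prep$a))
  Mk <- diag(k) + t * prep$G[S, S, drop = FALSE]
  chM <- chol((Mk + t(Mk)) / 2)
  wS <- prep$w[S]
  quad <- prep$a - t * sum(wS * chol_solve(chM, wS))
  -0.5 * (prep$d * log(2 * pi) + prep$logdetC0 +
            2 * sum(log(diag(chM))) + quad)
}

#' Log likelihood of the summary data given a causal configuration
#'
#' Multivariate-normal log density of `xi` at mean 0 with covariance
#' `R + R (d s^2 diag(gamma)) R`. When `R` itself is not positive definite
#' (typical when samples < d), a jitter `eps = 1e-8 trace(R)/d` (escalated up
#' to 1e8 x) is added to `R` before composing the covariance; the MCMC uses
#' the identical convention, so chain target and this function agree exactly.
#'
#' @param xi summary z-value vector.
#' @param R eigengene correlation matrix.
#' @param gamma binary causal vector.
#' @param s scale hyperparameter.
#' @param d dimension (defaults to `length(xi)`).
#' @return Log density (scalar).
#' @export
log_likelihood <- function(xi, R, gamma, s, d = length(xi)) {
  prep <- finemap_prep(xi, R)
  ll_active(prep, which(gamma == 1), d * s^2)
}

#' Fine-mapping hyperparameters
#'
#' @param s initial scale hyperparameter (default 0.05).
#' @param n_steps Metropolis steps (default 1e5).
#' @param burn_in discarded initial steps (default 1e3).
#' @param seed integer seed.
#' @param r causal-set size for `selected` (default 50; e.g. 10 for a trait
#'   with few causal dimensions).
#' @param update_s propose log-normal random-walk updates of `s` every
#'   `s_every` steps (flat prior on `s`, Jacobian-corrected); set `FALSE` to
#'   fix `s`.
#' @param s_every propose `s` every this many steps (default 10).
#' @param s_prop_sd sd of the log-normal proposal (default 0.1).
#' @param store_every keep every `store_every`-th post-burn-in draw in
#'   `samples` (PIPs always use every post-burn-in state); default keeps
#'   about 1000 draws.
#' @return List of class `finemap_hyper`.
#' @export
finemap_hyper <- function(s = 0.05, n_steps = 1e5, burn_in = 1e3, seed = 1L,
                          r = 50, update_s = TRUE, s_every = 10L,
                          s_prop_sd = 0.1, store_every = NULL) {
  if (s <= 0) stopf("s must be > 0")
  if (burn_in >= n_steps) stopf("burn_in must be < n_steps")
  if (is.null(store_every))
    store_every <- max(1L, as.integer((n_steps - burn_in) %/% 1000))
  structure(list(s = s, n_steps = as.integer(n_steps),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 r = as.integer(r), update_s = isTRUE(update_s),
                 s_every = as.integer(s_every), s_prop_sd = s_prop_sd,
                 store_every = as.integer(store_every)),
            class = "finemap_hyper")
}

#' Metropolis MCMC over causal configurations
#'
#' Each step flips one uniformly chosen coordinate of `gamma`; every
#' `s_every`-th step additionally proposes `s' = s exp(N(0, s_prop_sd))` with
#' the Jacobian-corrected acceptance ratio. The target is
#' `exp(log_prior + log_likelihood)`. The chain starts at `gamma = 0` and the
#' initial `s`; burn-in states are discarded and posterior inclusion
#' probabilities are the post-burn-in means of each `gamma_i`.
#'
#' @param xi summary z-value vector.
#' @param R eigengene correlation matrix.
#' @param hyper a [finemap_hyper()].
#' @return Object of class `finemap_result`: `pip`, `samples` (thinned draws,
#'   rows = draws), `s_trace`, `xi`, `R`, `selected` (top-r indices),
#'   `acceptance_rate`, `hyper`.
#' @export
run_mcmc <- function(xi, R, hyper = finemap_hyper()) {
  d <- length(xi)
  prep <- finemap_prep(xi, R)
  s <- hyper$s
  t_cur <- d * s^2
  S <- integer(0)
  gamma <- integer(d)
  ll_cur <- ll_active(prep, S, t_cur)
  lp_cur <- log_prior(gamma, d)
  if (!is.finite(ll_cur + lp_cur)) stopf("non-finite target at initialization")
  n_keep <- hyper$n_steps - hyper$burn_in
  pip_sum <- numeric(d)
  s_trace <- numeric(hyper$n_steps)
  stored <- matrix(0L, nrow = ceiling(n_keep / hyper$store_every), ncol = d)
  n_stored <- 0L
  n_acc <- 0L
  with_seed(hyper$seed, {
    flip_idx <- sample.int(d, hyper$n_steps, replace = TRUE)
    for (step in seq_len(hyper$n_steps)) {
      i <- flip_idx[step]
      S_new <- if (gamma[i] == 1L) S[S != i] else sort(c(S, i))
      gnew <- gamma; gnew[i] <- 1L - gnew[i]
      ll_new <- ll_active(prep, S_new, t_cur)
      lp_new <- log_prior(gnew, d)
      if (log(runif(1)) < (ll_new + lp_new) - (ll_cur + lp_cur)) {
        gamma <- gnew; S <- S_new; ll_cur <- ll_new; lp_cur <- lp_new
        n_acc <- n_acc + 1L
      }
      if (hyper$update_s && step %% hyper$s_every == 0L) {
        s_prop <- s * exp(rnorm(1, 0, hyper$s_prop_sd))
        t_prop <- d * s_prop^2
        ll_prop <- ll_active(prep, S, t_prop)
        if (log(runif(1)) < ll_prop - ll_cur + log(s_prop / s)) {
          s <- s_prop; t_cur <- t_prop; ll_cur <- ll_prop
        }
      }
      s_trace[step] <- s
      if (step > hyper$burn_in) {
        pip_sum <- pip_sum + gamma
        kept <- step - hyper$burn_in
        if (kept %% hyper$store_every == 1L || hyper$store_every == 1L) {
          n_stored <- n_stored + 1L
          stored[n_stored, ] <- gamma
        }
      }
    }
  })
  pip <- pip_sum / n_keep
  res <- structure(list(pip = pip,
                        samples = stored[seq_len(n_stored), , drop = FALSE],
                        s_trace = s_trace, xi = xi, R = R,
                        acceptance_rate = n_acc / hyper$n_steps,
                        hyper = hyper),
                   class = "finemap_result")
  res$selected <- select_causal(res, min(hyper$r, d))
  res
}

#' Exact posterior inclusion probabilities by exhaustive enumeration
#'
#' Enumerates all `2^d` causal configurations at fixed `s` (the independent
#' oracle for small d; feasible for d <= 15 or so).
#'
#' @param xi,R summary data.
#' @param s fixed scale hyperparameter.
#' @return Numeric d-vector of exact PIPs.
#' @export
exact_pip <- function(xi, R, s = 0.05) {
  d <- length(xi)
  if (d > 20) stopf("exhaustive enumeration limited to d <= 20")
  prep <- finemap_prep(xi, R)
  t <- d * s^2
  configs <- as.matrix(expand.grid(rep(list(0:1), d)))
  logw <- apply(configs, 1, function(g)
    log_prior(g, d) + ll_active(prep, which(g == 1), t))
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  as.numeric(crossprod(configs, w))
}

#' Select the top-r causal eigengenes by PIP
#'
#' Indices of the r largest posterior inclusion probabilities, in descending
#' PIP order with ties broken by the lower index.
#'
#' @param result a `finemap_result` (or a bare PIP vector).
#' @param r number of eigengenes to select.
#' @return Integer vector of length r.
#' @export
select_causal <- function(result, r) {
  pip <- if (inherits(result, "finemap_result")) result$pip else as.numeric(result)
  if (r > length(pip)) stopf("r = %d exceeds d = %d", r, length(pip))
  order(-pip, seq_along(pip))[seq_len(r)]
}

#' Classification accuracy along an eigengene ordering
#'
#' For each prefix length i of `order`, fits the ridge logistic model on the
#' first i ordered eigengenes and records in-sample accuracy (prefix 0 gives
#' the majority-class rate). Used to compare causal-PIP, singular-value, and
#' random orderings.
#'
#' @param X samples x d matrix or `projected_data`.
#' @param labels binary vector.
#' @param order eigengene index ordering (a permutation prefix).
#' @param ridge ridge penalty forwarded to [fit_logistic()].
#' @return data.frame with columns `prefix`, `accuracy`.
#' @export
causal_order_accuracy_curve <- function(X, labels, order, ridge = 1) {
  if (inherits(X, "projected_data")) X <- X$X
  y <- as.numeric(labels)
  acc <- numeric(length(order) + 1)
  acc[1] <- max(mean(y == 0), mean(y == 1))
  for (i in seq_along(order)) {
    fit <- fit_logistic(X[, order[seq_len(i)], drop = FALSE], y, ridge = ridge)
    acc[i + 1] <- fit$accuracy
  }
  data.frame(prefix = 0:length(order), accuracy = acc)
}

#' Full fine-mapping pipeline over a projected matrix
#'
#' Convenience wrapper: ridge logistic fit, summary statistics, and the
#' Metropolis chain.
#'
#' @param X samples x d matrix or `projected_data`.
#' @param labels binary phenotype vector.
#' @param hyper a [finemap_hyper()].
#' @param ridge ridge penalty for the logistic fit.
#' @return The `finemap_result`, with the `regression_fit` attached as `fit`.
#' @export
finemap_eigengenes <- function(X, labels, hyper = finemap_hyper(), ridge = 1) {
  fit <- fit_logistic(X, labels, ridge = ridge)
  if (inherits(X, "projected_data")) X <- X$X
  d <- ncol(X)
  xi <- z_value(X, fit$zeta, d)
  R <- correlation_matrix(X, fit$sigma2, d)
  res <- run_mcmc(xi, R, hyper)
  res$fit <- fit
  res
}
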