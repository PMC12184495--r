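#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom optim pnorm qnorm var sd quantile
#' @importFrom utils head tail
NULL

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards. All seeded operations in the package flow
# through this single gate so stages are reproducible in isolation.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# integer-safe seed derivation for sub-streams (keeps values < 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647L) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

# column variances without matrixStats
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(NA_real_, ncol(x)))
  mu <- colMeans(x)
  (colSums(x * x) - n * mu^2) / (n - 1)
}

is_binary01 <- function(x) all(x %in% c(0, 1))
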