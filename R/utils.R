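#' @importFrom rlang .data abort warn
#' @importFrom stats rbeta rbinom rchisq rnorm runif quantile var cor cov
#'   dnorm qnorm sd setNames
#' @importFrom utils head tail
NULL

# Trait order used throughout: egg production, meat production, overall health.
TRAITS <- c("egg", "meat", "health")

clamp01 <- function(p) pmin(pmax(p, 0), 1)

#' Derive independent stream seeds from a master seed
#'
#' All randomness in the simulator flows from a single integer seed.  Stream
#' seeds (per replicate, and within a replicate for the architecture/history
#' phase vs the breeding phase) are derived by drawing from a generator seeded
#' with the master seed, so that paired scenario arms can share founder seeds
#' while their breeding phases remain independent experiments.
#'
#' @param seed Master integer seed.
#' @param n Number of stream seeds to derive.
#' @return Integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

as_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 0 || x != round(x)) {
    abort(sprintf("`%s` must be a single non-negative integer", name))
  }
  as.integer(x)
}

# Draw n rows from N(0, Sigma) given the upper Cholesky factor of Sigma.
rmvn <- function(n, chol_sigma) {
  k <- ncol(chol_sigma)
  matrix(rnorm(n * k), n, k) %*% chol_sigma
}
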