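#' Initial prediction reliabilities
#'
#' Genomic prediction reliability starts at 0.7 for the two production
#' traits and 0.5 for overall health.
#'
#' @return Named numeric 3-vector of squared accuracies.
#' @export
initial_reliability <- function() {
  c(egg = 0.7, meat = 0.7, health = 0.5)
}

#' Reliability recursion
#'
#' `r2 <- r2 + 0.05 (1 - r2)` per trait and generation, mimicking the growth
#' of a genomic reference population; 1 is the fixed point.
#'
#' @param r2 Per-trait reliabilities in `[0, 1]`.
#' @param gain Fraction of the remaining unreliability recovered per
#'   generation.
#' @return Updated reliabilities.
#' @export
update_reliability <- function(r2, gain = 0.05) {
  stopifnot(all(r2 >= 0 & r2 <= 1))
  r2 + gain * (1 - r2)
}

#' Simulate estimated breeding values
#'
#' EBVs are not estimated from data; they are drawn from the conditional
#' distribution implied by a bivariate-normal (TBV, EBV) model with squared
#' accuracy `r2`: `EBV | TBV ~ N(r2 TBV, r2 (1 - r2) V_A)`, independently per
#' trait.  Under this model the squared correlation between EBV and TBV is
#' `r2` and the regression of TBV on EBV has slope 1.
#'
#' @param tbv `n x 3` matrix of true breeding values.
#' @param r2 Per-trait reliabilities.
#' @param v_a Per-trait additive variance of the current cohort.
#' @return `n x 3` matrix of EBVs.
#' @export
simulate_ebv <- function(tbv, r2, v_a) {
  if (any(v_a < 0)) abort("additive variance must be non-negative")
  stopifnot(length(r2) == ncol(tbv), length(v_a) == ncol(tbv))
  sds <- sqrt(r2 * (1 - r2) * v_a)
  noise <- matrix(rnorm(length(tbv)), nrow(tbv)) %*% diag(sds)
  out <- sweep(tbv, 2, r2, `*`) + noise
  colnames(out) <- colnames(tbv)
  out
}

#' Selection-index value
#'
#' @param values `n x 3` matrix (or 3-vector) of trait values.
#' @param weights Index weights (see [line_weights()]).
#' @return Weighted sum per animal.
#' @export
index_value <- function(values, weights) {
  if (is.null(dim(values))) values <- matrix(values, 1)
  drop(values %*% as.numeric(weights))
}
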