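#' Project a vector onto the scaled simplex
#'
#' Euclidean projection onto `{c : c >= 0, sum(c) = s}` (used by the
#' brute-force OCS oracle in the tests and as a fallback start point).
#'
#' @param v Numeric vector.
#' @param s Target sum.
#' @return Projected vector.
#' @export
project_simplex <- function(v, s = 0.5) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u) - s
  rho <- max(which(u - css / seq_along(u) > 0))
  pmax(v - css[rho] / rho, 0)
}

# Inner solver: maximize u'c - lambda * (c'Qc + 2 r'c) over the scaled
# simplex, via quadprog.  A tiny ridge keeps D positive definite when Q is
# only PSD.
solve_penalized_qp <- function(u, Q, r, lambda, s = 0.5, ridge = 1e-10) {
  n <- length(u)
  D <- 2 * lambda * Q + diag(ridge, n)
  A <- cbind(rep(1, n), diag(n))
  sol <- quadprog::solve.QP(D, u - 2 * lambda * r, A,
                            c(s, rep(0, n)), meq = 1)
  pmax(sol$solution, 0)
}

#' Optimum contributions of sires under a coancestry-rate constraint
#'
#' Maximizes the expected index merit of the next generation, `c'u`, over
#' male genetic contributions (females contribute equally), subject to the
#' constraint that the mean kinship of the next generation does not exceed
#' `Kbar + dF (1 - Kbar)` with `dF = 1/(2 Ne)` -- the standard cap that
#' maintains an effective population size of `Ne`.  With fixed female
#' contributions the constraint is a convex quadratic in the male
#' contributions; the problem is solved by bisecting the Lagrange multiplier
#' of the quadratic constraint, with a positive-definite QP
#' ([quadprog::solve.QP()]) at each multiplier.
#'
#' Edge cases: when the unconstrained optimum (all male weight on the
#' top-EBV male) already satisfies the cap, it is returned; when even the
#' minimum-coancestry contribution vector violates the cap (deep into an
#' inbred run), that vector is returned with a warning so long replicates
#' stay alive.
#'
#' @param u Index EBVs of the candidate males.
#' @param kinship Kinship matrix over all selection candidates.
#' @param male_idx,female_idx Row indices of male and female candidates in
#'   `kinship`.
#' @param ne Target effective population size.
#' @param kbar Current mean kinship (default the mean of `kinship`).
#' @param tol Constraint tolerance, relative to `1 - kbar`.
#' @param lambda_init Optional warm start for the constraint multiplier
#'   (e.g. the `lambda` returned for the previous generation); cuts the
#'   bisection cost substantially in long runs.
#' @return List: `contributions` (per-male, summing to 0.5), `constraint`
#'   (attained next-generation mean kinship), `bound`, `lambda`, and
#'   `feasible`.
#' @export
optimum_contributions <- function(u, kinship, male_idx, female_idx,
                                  ne = 100, kbar = mean(kinship),
                                  tol = 1e-6, lambda_init = NULL) {
  stopifnot(length(u) == length(male_idx))
  dF <- 1 / (2 * ne)
  bound <- kbar + dF * (1 - kbar)
  nf <- length(female_idx)
  cf <- 0.5 / nf
  Q <- kinship[male_idx, male_idx, drop = FALSE]
  r <- cf * rowSums(kinship[male_idx, female_idx, drop = FALSE])
  const <- cf^2 * sum(kinship[female_idx, female_idx])
  qval <- function(c) drop(c %*% Q %*% c + 2 * sum(r * c) + const)
  eps <- tol * max(1 - kbar, 1e-3)

  # Unconstrained optimum: all male weight on the best male (ties by id).
  c_lp <- numeric(length(u))
  c_lp[which.max(u)] <- 0.5
  if (qval(c_lp) <= bound + eps) {
    return(list(contributions = c_lp, constraint = qval(c_lp),
                bound = bound, lambda = 0, feasible = TRUE))
  }

  # Minimum-coancestry solution (lambda -> Inf limit).
  c_min <- solve_penalized_qp(numeric(length(u)), Q, r, lambda = 1)
  if (qval(c_min) > bound + eps) {
    warn("coancestry constraint infeasible; returning minimum-coancestry contributions")
    return(list(contributions = c_min, constraint = qval(c_min),
                bound = bound, lambda = Inf, feasible = FALSE))
  }

  lo <- 0
  hi <- if (is.null(lambda_init) || !is.finite(lambda_init) || lambda_init <= 0) {
    1
  } else {
    lambda_init / 4
  }
  for (k in 1:60) {
    if (qval(solve_penalized_qp(u, Q, r, hi)) <= bound + eps) break
    lo <- hi
    hi <- hi * 4
  }
  c_hi <- solve_penalized_qp(u, Q, r, hi)
  for (k in 1:50) {
    if (hi - lo < 0.01 * hi) break
    mid <- (lo + hi) / 2
    c_mid <- solve_penalized_qp(u, Q, r, mid)
    if (qval(c_mid) <= bound + eps) {
      hi <- mid
      c_hi <- c_mid
    } else {
      lo <- mid
    }
  }
  list(contributions = c_hi, constraint = qval(c_hi), bound = bound,
       lambda = hi, feasible = TRUE)
}

#' Allocate matings with equal dam contributions
#'
#' Offspring counts per dam deviate by at most one (the surplus after equal
#' division is assigned to randomly chosen dams); each offspring's sire is
#' drawn with probability proportional to twice his contribution; pairing is
#' otherwise random.
#'
#' @param contributions Per-male contribution vector (sums to 0.5).
#' @param male_idx,dam_idx Candidate indices the returned pairs refer to.
#' @param n_offspring Number of offspring to produce.
#' @return Tibble with one row per offspring: `sire`, `dam`.
#' @export
allocate_matings <- function(contributions, male_idx, dam_idx,
                             n_offspring = 500) {
  if (length(male_idx) == 0 || length(dam_idx) == 0) {
    abort("empty parent pool")
  }
  nd <- length(dam_idx)
  counts <- rep(n_offspring %/% nd, nd)
  extra <- n_offspring %% nd
  if (extra > 0) {
    bump <- sample.int(nd, extra)
    counts[bump] <- counts[bump] + 1
  }
  dams <- sample(rep(dam_idx, counts))
  pr <- 2 * contributions
  if (sum(pr) <= 0) abort("contributions must have positive mass")
  sires <- male_idx[sample.int(length(male_idx), n_offspring,
                               replace = TRUE, prob = pr)]
  tibble::tibble(sire = sires, dam = dams)
}
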