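#' Trait architecture configuration
#'
#' Fixes the founder genome size and the distribution of pleiotropic QTL
#' effects on the three traits (egg production, meat production, overall
#' health).  Defaults encode the stated world of the simulator: 5000 unlinked
#' SNPs of which 500 are QTL, effects from a truncated trivariate t
#' distribution (inverse-chi-square scale with `dof` degrees of freedom,
#' correlation matrix with off-diagonals -0.4 / -0.2 / -0.2, rows with norm
#' below the 33% quantile rejected), and founder variance components per
#' trait summing to a phenotypic variance of 1 (heritabilities 0.4, 0.4,
#' 0.2, of which the explicit QTL explain 0.27, 0.27 and 0.14).
#'
#' @param n_snps Number of unlinked SNPs in the founder genome.
#' @param n_qtl Number of SNPs that are QTL with explicit effects.
#' @param dof Degrees of freedom of the inverse-chi-square scale mixing
#'   distribution.
#' @param effect_correlations 3x3 correlation matrix of QTL effects across
#'   traits (egg, meat, health).
#' @param rejection_quantile Rows of effects with norm below this quantile of
#'   the untruncated norm distribution are resampled.
#' @param qtl_variances Per-trait founder additive variance explained by the
#'   explicit QTL.
#' @param polygenic_variances Per-trait founder polygenic additive variance.
#' @param residual_variances Per-trait environmental variance.
#' @param founder_beta Shape parameters (alpha, beta) of the Beta distribution
#'   of founder allele frequencies.
#' @param freq_clip Founder frequencies are clipped to
#'   `[freq_clip, 1 - freq_clip]` to avoid degenerate Hardy-Weinberg draws.
#' @param threshold_draws Monte-Carlo sample size used to estimate the norm
#'   rejection threshold (no closed form exists).
#' @param threshold_seed Dedicated seed for the threshold pre-sample, so the
#'   threshold is identical across replicates of a run.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(n_snps = 5000,
                        n_qtl = 500,
                        dof = 4,
                        effect_correlations = matrix(
                          c(1, -0.4, -0.2,
                            -0.4, 1, -0.2,
                            -0.2, -0.2, 1), 3, 3),
                        rejection_quantile = 0.33,
                        qtl_variances = c(egg = 0.27, meat = 0.27, health = 0.14),
                        polygenic_variances = c(egg = 0.13, meat = 0.13, health = 0.06),
                        residual_variances = c(egg = 0.6, meat = 0.6, health = 0.8),
                        founder_beta = c(0.5, 0.5),
                        freq_clip = 1e-6,
                        threshold_draws = 1e6,
                        threshold_seed = 104729L) {
  n_snps <- as_count(n_snps, "n_snps")
  n_qtl <- as_count(n_qtl, "n_qtl")
  S <- as.matrix(effect_correlations)
  if (!isTRUE(all.equal(S, t(S))) || any(diag(S) != 1)) {
    abort("`effect_correlations` must be a symmetric correlation matrix with unit diagonal")
  }
  if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    abort("`effect_correlations` must be positive definite")
  }
  if (rejection_quantile < 0 || rejection_quantile > 1) {
    abort("`rejection_quantile` must be in [0, 1]")
  }
  vsum <- qtl_variances + polygenic_variances + residual_variances
  if (!isTRUE(all.equal(unname(vsum), rep(1, 3)))) {
    abort("per-trait variance components must sum to 1 (founder phenotypic scale)")
  }
  structure(list(
    n_snps = n_snps, n_qtl = n_qtl, dof = dof,
    effect_correlations = S,
    rejection_quantile = rejection_quantile,
    qtl_variances = setNames(as.numeric(qtl_variances), TRAITS),
    polygenic_variances = setNames(as.numeric(polygenic_variances), TRAITS),
    residual_variances = setNames(as.numeric(residual_variances), TRAITS),
    founder_beta = founder_beta,
    freq_clip = freq_clip,
    threshold_draws = threshold_draws,
    threshold_seed = as.integer(threshold_seed)
  ), class = "arch_config")
}

#' Sample founder allele frequencies and QTL positions
#'
#' Founder frequencies follow Beta(alpha, beta) (default the U-shaped
#' Beta(0.5, 0.5), typical of diverged populations) and are clipped away from
#' exact fixation.  QTL positions are a uniform draw without replacement.
#'
#' @param config An [arch_config()].
#' @return An object of class `founder_genome` with elements `frequencies`
#'   (length `n_snps`), `qtl_indices` and `qtl_freq`.
#' @export
sample_founder_frequencies <- function(config = arch_config()) {
  if (config$n_qtl > config$n_snps) {
    abort("`n_qtl` cannot exceed `n_snps`")
  }
  p <- rbeta(config$n_snps, config$founder_beta[1], config$founder_beta[2])
  p <- pmin(pmax(p, config$freq_clip), 1 - config$freq_clip)
  qtl <- sort(sample.int(config$n_snps, config$n_qtl))
  structure(list(frequencies = p, qtl_indices = qtl, qtl_freq = p[qtl]),
            class = "founder_genome")
}

# Cache for the Monte-Carlo norm threshold; keyed by the config values that
# determine the norm distribution so 100 replicates pay for one pre-sample.
the_threshold_cache <- new.env(parent = emptyenv())

#' Rejection threshold for small-effect QTL
#'
#' The QTL effect vector is `a | tau^2 ~ N3(0, tau^2 Sigma)` with
#' `tau^2 ~ inv-chi-square(dof)`.  Rows whose Euclidean norm falls below the
#' `rejection_quantile` quantile of the marginal norm distribution are
#' resampled (such loci are absorbed into the polygenic term instead).  The
#' quantile has no closed form and is estimated once per configuration from a
#' large Monte-Carlo pre-sample under a dedicated seed.
#'
#' @param config An [arch_config()].
#' @return The threshold (scalar); 0 when `rejection_quantile` is 0 and `Inf`
#'   when it is 1.
#' @export
norm_rejection_threshold <- function(config = arch_config()) {
  if (config$rejection_quantile <= 0) return(0)
  if (config$rejection_quantile >= 1) return(Inf)
  key <- paste(config$dof, config$rejection_quantile, config$threshold_draws,
               config$threshold_seed,
               paste(signif(config$effect_correlations, 12), collapse = ","),
               sep = "|")
  hit <- the_threshold_cache[[key]]
  if (!is.null(hit)) return(hit)
  L <- chol(config$effect_correlations)
  thr <- withr::with_seed(config$threshold_seed, {
    n <- as.integer(config$threshold_draws)
    z <- rmvn(n, L)
    tau <- sqrt(1 / rchisq(n, df = config$dof))
    unname(quantile(tau * sqrt(rowSums(z^2)), config$rejection_quantile))
  })
  the_threshold_cache[[key]] <- thr
  thr
}

#' Sample pleiotropic QTL effects
#'
#' Draws one effect row per QTL from the truncated trivariate t distribution
#' (see [norm_rejection_threshold()]) and then rescales each trait column by a
#' scalar so that the additive variance contributed by the QTL at founder
#' frequencies, `sum_q 2 p_q (1 - p_q) a_qk^2`, exactly equals the configured
#' per-trait QTL variance.
#'
#' @param genome A [sample_founder_frequencies()] result.
#' @param config An [arch_config()].
#' @param max_batches Bound on resampling batches before a sampling error is
#'   raised (only reachable for pathological configurations).
#' @return An object of class `qtl_effects`: `a` (`n_qtl` x 3 matrix, columns
#'   egg/meat/health), `tau2`, `founder_freq`, `threshold` and the per-trait
#'   `scaling` factors applied.
#' @export
sample_qtl_effects <- function(genome, config = arch_config(), max_batches = 1000L) {
  stopifnot(inherits(genome, "founder_genome"))
  n <- config$n_qtl
  thr <- norm_rejection_threshold(config)
  L <- chol(config$effect_correlations)
  a <- matrix(NA_real_, 0, 3)
  tau2 <- numeric(0)
  batches <- 0L
  while (nrow(a) < n) {
    batches <- batches + 1L
    if (batches > max_batches) {
      abort("norm rejection loop failed to accept enough QTL effect rows")
    }
    m <- max(2L * (n - nrow(a)), 64L)
    t2 <- 1 / rchisq(m, df = config$dof)
    cand <- sqrt(t2) * rmvn(m, L)
    keep <- sqrt(rowSums(cand^2)) >= thr
    a <- rbind(a, cand[keep, , drop = FALSE])
    tau2 <- c(tau2, t2[keep])
  }
  a <- a[seq_len(n), , drop = FALSE]
  tau2 <- tau2[seq_len(n)]
  p <- genome$qtl_freq
  w <- 2 * p * (1 - p)
  scaling <- sqrt(config$qtl_variances / colSums(w * a^2))
  a <- sweep(a, 2, scaling, `*`)
  colnames(a) <- TRAITS
  structure(list(a = a, tau2 = tau2, founder_freq = p,
                 threshold = thr, scaling = scaling),
            class = "qtl_effects")
}

#' @export
tidy.qtl_effects <- function(x, ...) {
  tibble::tibble(
    qtl_id = seq_len(nrow(x$a)),
    founder_freq = x$founder_freq,
    a_egg = x$a[, "egg"], a_meat = x$a[, "meat"], a_health = x$a[, "health"]
  )
}

#' Write / read a QTL architecture table
#'
#' Serializes the per-QTL founder frequencies and effects as delimited text
#' (`qtl_id, founder_freq, a_egg, a_meat, a_health`) for inspection and test
#' fixtures.
#'
#' @param effects A `qtl_effects` object.
#' @param path File path.
#' @return `path`, invisibly (writer); a `qtl_effects` object (reader).
#' @export
write_architecture <- function(effects, path) {
  readr::write_csv(generics::tidy(effects), path)
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  a <- as.matrix(tb[, c("a_egg", "a_meat", "a_health")])
  colnames(a) <- TRAITS
  structure(list(a = a, tau2 = rep(NA_real_, nrow(a)),
                 founder_freq = tb$founder_freq,
                 threshold = NA_real_, scaling = rep(NA_real_, 3)),
            class = "qtl_effects")
}

#' Beneficial allele of each QTL
#'
#' The beneficial allele is the one whose substitution effect on the
#' dual-purpose selection index is positive; an exact zero is broken toward
#' the counted allele.
#'
#' @param effects A `qtl_effects` object (or a plain effects matrix).
#' @param weights Index weights, default the dual-purpose weights.
#' @return Logical vector: `TRUE` when the counted allele is beneficial.
#' @export
beneficial_is_counted <- function(effects, weights = line_weights("dual")) {
  a <- if (inherits(effects, "qtl_effects")) effects$a else effects
  drop(a %*% weights) >= 0
}
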