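#' Selection-index weights of the breeding lines
#'
#' Historic layer and broiler lines weight their main production trait at
#' 0.56, the other production trait and overall health at 0.22 each; the
#' dual-purpose index weights the two production traits equally (0.375) and
#' overall health at 0.25.
#'
#' @param line `"layer"`, `"broiler"` or `"dual"`.
#' @return Named numeric 3-vector (egg, meat, health) summing to 1.
#' @export
line_weights <- function(line = c("layer", "broiler", "dual")) {
  line <- match.arg(line)
  w <- switch(line,
    layer   = c(0.56, 0.22, 0.22),
    broiler = c(0.22, 0.56, 0.22),
    dual    = c(0.375, 0.375, 0.25)
  )
  setNames(w, TRAITS)
}

#' History-phase configuration
#'
#' @param n_generations Number of historic generations of divergent selection
#'   separating the two commercial lines from their common founder.
#' @param intensity Selection intensity `i` of the truncation selection.
#' @return An object of class `history_config`.
#' @export
history_config <- function(n_generations = 100, intensity = 1.4) {
  stopifnot(n_generations >= 0, intensity > 0)
  structure(list(n_generations = as.integer(n_generations),
                 intensity = intensity),
            class = "history_config")
}

#' Allele substitution effect on a selection index
#'
#' @param a Effects matrix (`n_qtl` x 3) or a single 3-vector.
#' @param weights Index weights.
#' @return `alpha_q = sum_k w_k a_qk` per QTL.
#' @export
index_substitution_effect <- function(a, weights) {
  if (is.null(dim(a))) a <- matrix(a, 1)
  drop(a %*% as.numeric(weights))
}

# QTL additive covariance of the three traits at frequencies p.
qtl_cov <- function(p, a) crossprod(a, (2 * p * (1 - p)) * a)

# Polygenic additive covariance given per-trait polygenic variances.
poly_cov <- function(v_poly, config) {
  sp <- sqrt(v_poly)
  outer(sp, sp) * config$effect_correlations
}

index_sd <- function(cov_mat, weights) {
  v <- drop(crossprod(weights, cov_mat %*% weights))
  if (v <= 0) abort("non-positive index variance")
  sqrt(v)
}

#' Expected one-generation allele-frequency change under index truncation
#' selection
#'
#' The classical result for selection on a normally distributed index: the
#' expected frequency of an allele with substitution effect `alpha` on the
#' index moves by `i p (1 - p) alpha / sigma_I` in one generation, where `i`
#' is the selection intensity and `sigma_I` the phenotypic standard deviation
#' of the index.  Fixation is absorbing; the result is clamped to `[0, 1]`.
#'
#' @param p Current allele frequency (vectorized).
#' @param alpha Substitution effect(s) on the index.
#' @param i Selection intensity.
#' @param sigma_index Phenotypic SD of the index (positive scalar).
#' @return Updated frequency.
#' @export
expected_frequency_update <- function(p, alpha, i, sigma_index) {
  stopifnot(all(p >= 0 & p <= 1))
  if (sigma_index <= 0) abort("`sigma_index` must be positive")
  clamp01(p + i * p * (1 - p) * alpha / sigma_index)
}

#' Analytic divergence of the layer and broiler lines
#'
#' Runs the deterministic 100-generation history: each line is truncation
#' selected on its own index (layer vs broiler weights) with intensity `i`.
#' Per-QTL frequencies follow the expected-change recursion of
#' [expected_frequency_update()], with the phenotypic index SD recomputed
#' every generation from the eroding QTL variance, a polygenic variance that
#' shrinks per trait in proportion to the same trait's QTL variance, and the
#' fixed residual variance.  Genetic drift is disregarded, so generation 0
#' represents expected line means.  Cumulative genetic change per trait
#' accumulates as the QTL response `sum_q 2 dp_q a_qk` plus the polygenic
#' response `i cov(poly_k, I) / sigma_I` per generation, expressed in founder
#' (generation -100) phenotypic SD units.  The polygenic response must be
#' included: the QTL-only response is bounded by its exhaustion limit (~15
#' SD for egg production) and cannot alone account for the ~20 SD improvement
#' of the main production trait.
#'
#' @param genome A [sample_founder_frequencies()] result.
#' @param effects A [sample_qtl_effects()] result.
#' @param config An [arch_config()].
#' @param history A [history_config()].
#' @return List with elements `layer` and `broiler`, each a `line_state`:
#'   `qtl_freq` (generation-0 QTL frequencies, also frozen as
#'   `reference_frequencies` for centering QTL breeding values),
#'   `frequencies` (all SNPs), and `trait_means` (generation-0 means relative
#'   to generation -100).
#' @export
run_divergent_selection <- function(genome, effects,
                                    config = arch_config(),
                                    history = history_config()) {
  vq0 <- qtl_variance_at(genome$qtl_freq, effects)
  lines <- purrr::map(c(layer = "layer", broiler = "broiler"), function(id) {
    w <- line_weights(id)
    alpha <- index_substitution_effect(effects$a, w)
    p <- genome$qtl_freq
    mu <- setNames(numeric(3), TRAITS)
    for (g in seq_len(history$n_generations)) {
      c_qtl <- qtl_cov(p, effects$a)
      v_poly <- config$polygenic_variances * diag(c_qtl) / vq0
      c_poly <- poly_cov(v_poly, config)
      sig <- index_sd(c_qtl + c_poly + diag(config$residual_variances), w)
      p_new <- expected_frequency_update(p, alpha, history$intensity, sig)
      mu <- mu + colSums(2 * (p_new - p) * effects$a) +
        history$intensity * drop(c_poly %*% w) / sig
      p <- p_new
    }
    freqs <- genome$frequencies
    freqs[genome$qtl_indices] <- p
    structure(list(line_id = id, frequencies = freqs, qtl_freq = p,
                   reference_frequencies = p, trait_means = mu),
              class = "line_state")
  })
  lines
}

#' Additive variance explained by the QTL at given frequencies
#'
#' @param p QTL allele frequencies.
#' @param effects A `qtl_effects` object.
#' @return Named per-trait variance `sum_q 2 p (1 - p) a_qk^2`.
#' @export
qtl_variance_at <- function(p, effects) {
  setNames(colSums(2 * p * (1 - p) * effects$a^2), TRAITS)
}

#' Generation-0 polygenic variance of a line
#'
#' The polygenic variance is reduced from its founder value in proportion to
#' the loss of QTL variance over the historic phase (an absolute reduction by
#' the same amount could go negative, so the proportional reading is used and
#' validated against the realized generation-0 heritabilities).
#'
#' @param line A `line_state`.
#' @param effects A `qtl_effects` object.
#' @param config An [arch_config()].
#' @return Named per-trait polygenic variance at generation 0.
#' @export
polygenic_variance_gen0 <- function(line, effects, config = arch_config()) {
  ratio <- qtl_variance_at(line$qtl_freq, effects) / config$qtl_variances
  config$polygenic_variances * ratio
}

#' Census of QTL fixed by historic selection
#'
#' Classifies fixed QTL (frequency within `eps` of 0 or 1) at generation 0:
#' fixed for the same allele in both lines; additionally fixed for the
#' dual-purpose-beneficial allele in the broiler line only; ditto for the
#' layer line only.
#'
#' @param layer,broiler `line_state`s at generation 0.
#' @param effects A `qtl_effects` object.
#' @param dual_weights Index weights defining the beneficial phase.
#' @param eps Fixation tolerance.
#' @return Tibble with columns `both_same_phase`, `broiler_only_beneficial`,
#'   `layer_only_beneficial`.
#' @export
count_fixed_qtl <- function(layer, broiler, effects,
                            dual_weights = line_weights("dual"),
                            eps = 1e-6) {
  ben_counted <- beneficial_is_counted(effects, dual_weights)
  class_line <- function(p) {
    list(fixed = p <= eps | p >= 1 - eps, high = p >= 1 - eps)
  }
  l <- class_line(layer$qtl_freq)
  b <- class_line(broiler$qtl_freq)
  both_same <- l$fixed & b$fixed & (l$high == b$high)
  ben_l <- l$fixed & (l$high == ben_counted)
  ben_b <- b$fixed & (b$high == ben_counted)
  tibble::tibble(
    both_same_phase = sum(both_same),
    broiler_only_beneficial = sum(ben_b & !both_same),
    layer_only_beneficial = sum(ben_l & !both_same)
  )
}

#' Write generation-0 line frequencies as delimited text
#'
#' @param layer,broiler `line_state`s.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_line_states <- function(layer, broiler, path) {
  readr::write_csv(tibble::tibble(
    snp_id = seq_along(layer$frequencies),
    freq_layer = layer$frequencies,
    freq_broiler = broiler$frequencies
  ), path)
  invisible(path)
}
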