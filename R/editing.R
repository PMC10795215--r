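#' Gene-editing configuration
#'
#' @param n_edits SNPs edited per edited male (0 disables editing).
#' @param n_edited_males Top sires (by optimum contribution) edited per
#'   generation.
#' @param offtarget_probability Per-edit chance of an off-target hit.
#' @param offtarget_effect Size of the heritable reduction of the polygenic
#'   health value per off-target hit (close to the 95% quantile of SNP
#'   effects on health).
#' @param maf_threshold SNPs below this minor allele frequency in the
#'   mapping cross cannot be estimated and are excluded from editing.
#' @param suggestive_noise Variance of the one-time error separating the
#'   suggestive from the true effect, as a fraction of the founder additive
#'   variance per trait (linkage confounding is approximated this way
#'   instead of simulating LD).
#' @param n_first,n_later Mapping-population cohort sizes: animals with
#'   phenotypes in the first generation and added per later generation.
#' @return An object of class `editing_config`.
#' @export
editing_config <- function(n_edits = 25,
                           n_edited_males = 25,
                           offtarget_probability = 0.01,
                           offtarget_effect = 0.05,
                           maf_threshold = 0.05,
                           suggestive_noise = 0.002,
                           n_first = 10000,
                           n_later = 2000) {
  stopifnot(n_edits >= 0, n_edited_males >= 0,
            offtarget_probability >= 0, offtarget_probability <= 1,
            maf_threshold >= 0, maf_threshold <= 0.5)
  structure(list(n_edits = as.integer(n_edits),
                 n_edited_males = as.integer(n_edited_males),
                 offtarget_probability = offtarget_probability,
                 offtarget_effect = offtarget_effect,
                 maf_threshold = maf_threshold,
                 suggestive_noise = suggestive_noise,
                 n_first = n_first, n_later = n_later),
            class = "editing_config")
}

#' Suggestive SNP effects
#'
#' In practice a SNP in complete LD with other loci has an effect estimate
#' that converges to a suggestive effect, not the true one.  The suggestive
#' effect is the true effect plus a one-time normal error with variance
#' `suggestive_noise` times the founder additive variance of the trait; it
#' is drawn once per replicate and never redrawn.
#'
#' @param effects A `qtl_effects` object.
#' @param config An [arch_config()].
#' @param edit_config An [editing_config()].
#' @return `n_qtl x 3` matrix of suggestive effects.
#' @export
make_suggestive_effects <- function(effects, config = arch_config(),
                                    edit_config = editing_config()) {
  v_add <- config$qtl_variances + config$polygenic_variances
  sds <- sqrt(edit_config$suggestive_noise * v_add)
  effects$a + matrix(rnorm(length(effects$a)), nrow(effects$a)) %*% diag(sds)
}

#' Single-generation SNP-effect estimate
#'
#' The hypothetical mapping study (a layer x broiler cross external to the
#' breeding line) yields, per generation, an estimate
#' `a_hat ~ N(a_sugg, V_P / (2 p (1 - p) N))` per QTL and trait.  The
#' `1 / (2 p (1 - p))` factor makes extreme-frequency SNPs less accurately
#' estimated; SNPs below the MAF threshold in the cross are inestimable
#' (`NA` rows) and excluded from editing.
#'
#' @param a_sugg Suggestive-effects matrix.
#' @param p_cross Per-QTL allele frequency in the mapping cross.
#' @param n_animals Phenotyped animals contributing to this generation's
#'   estimate.
#' @param v_p Phenotypic variance of each trait (approximately 1).
#' @param maf_threshold Estimability cutoff.
#' @return Matrix like `a_sugg`, with `NA` rows for inestimable QTL.
#' @export
generation_estimate <- function(a_sugg, p_cross, n_animals, v_p = 1,
                                maf_threshold = 0.05) {
  stopifnot(n_animals >= 1)
  estimable <- pmin(p_cross, 1 - p_cross) >= maf_threshold
  sd_q <- sqrt(v_p / (2 * p_cross * (1 - p_cross) * n_animals))
  est <- a_sugg + matrix(rnorm(length(a_sugg)), nrow(a_sugg)) * sd_q
  est[!estimable, ] <- NA_real_
  est
}

#' Pooled SNP-effect estimate
#'
#' The final estimate after `n` mapping generations is the cohort-size
#' weighted mean `(N_1 a_hat^1 + ... + N_n a_hat^n) / (N_1 + ... + N_n)`.
#'
#' @param estimates List of per-generation estimate matrices.
#' @param n_animals Cohort size per generation (recycled against
#'   `estimates`).
#' @return Pooled estimate matrix.
#' @export
pooled_estimate <- function(estimates, n_animals) {
  if (length(estimates) == 0) abort("no mapping generations recorded")
  n_animals <- rep_len(n_animals, length(estimates))
  Reduce(`+`, Map(`*`, estimates, n_animals)) / sum(n_animals)
}

# Incremental mapping-study state: weighted sums instead of the full
# history, so a 40-generation run carries O(1) state.
new_mapping_study <- function(effects, layer, broiler, config, edit_config) {
  p_cross <- (layer$qtl_freq + broiler$qtl_freq) / 2
  list(
    a_sugg = make_suggestive_effects(effects, config, edit_config),
    p_cross = p_cross,
    estimable = pmin(p_cross, 1 - p_cross) >= edit_config$maf_threshold,
    weighted_sum = NULL, total_n = 0
  )
}

advance_mapping_study <- function(study, edit_config) {
  n <- if (study$total_n == 0) edit_config$n_first else edit_config$n_later
  est <- generation_estimate(study$a_sugg, study$p_cross, n,
                             maf_threshold = edit_config$maf_threshold)
  est[!study$estimable, ] <- 0  # never used; keeps the sums NA-free
  if (is.null(study$weighted_sum)) {
    study$weighted_sum <- n * est
  } else {
    study$weighted_sum <- study$weighted_sum + n * est
  }
  study$total_n <- study$total_n + n
  study$pooled <- study$weighted_sum / study$total_n
  study$pooled[!study$estimable, ] <- NA_real_
  study
}

#' Choose edit targets for one animal
#'
#' QTL are ranked by the absolute estimated substitution effect on the
#' dual-purpose index, `|sum_k w_k a_hat_qk|`.  Inestimable QTL (low MAF in
#' the mapping cross) are skipped, as are QTL where the animal is already
#' homozygous for the estimated-beneficial allele; the search proceeds to
#' the next-best SNP until `n_edits` targets are found or candidates are
#' exhausted.
#'
#' @param genotype The animal's QTL allele counts.
#' @param pooled Pooled estimate matrix (`NA` rows inestimable).
#' @param weights Selection-index weights.
#' @param n_edits Number of edits sought.
#' @return Tibble with `qtl` (index) and `direction` (+1: add a counted
#'   allele; -1: remove one), at most `n_edits` rows.
#' @export
select_edit_targets <- function(genotype, pooled, weights, n_edits) {
  score <- drop(pooled %*% as.numeric(weights))
  ord <- order(abs(score), decreasing = TRUE, na.last = NA)
  beneficial_counted <- score >= 0
  editable <- ifelse(beneficial_counted[ord], genotype[ord] < 2L,
                     genotype[ord] > 0L)
  chosen <- ord[editable][seq_len(min(n_edits, sum(editable)))]
  tibble::tibble(qtl = chosen,
                 direction = ifelse(beneficial_counted[chosen], 1L, -1L))
}

#' Apply edits to selected sires
#'
#' Each target moves the animal one allele count toward the
#' estimated-beneficial allele.  Independently per edit, with probability
#' `offtarget_probability` the animal accrues an off-target penalty of
#' `offtarget_effect` on its polygenic health value (heritable via the
#' parent average).  Editing happens after contributions are computed and
#' before mating, so the sire's own (reported) TBV changes but its selection
#' does not.
#'
#' @param cohort The `cohort` holding the males.
#' @param male_rows Row indices of the males to edit.
#' @param study Mapping-study state with a `pooled` estimate.
#' @param weights Selection-index weights.
#' @param edit_config An [editing_config()].
#' @return List: the edited `cohort` and an `edit_log` tibble
#'   (`animal`, `qtl`, `direction`, `offtarget`).
#' @export
apply_edits <- function(cohort, male_rows, study, weights,
                        edit_config = editing_config()) {
  logs <- vector("list", length(male_rows))
  for (k in seq_along(male_rows)) {
    row <- male_rows[k]
    targets <- select_edit_targets(cohort$geno[row, ], study$pooled,
                                   weights, edit_config$n_edits)
    if (nrow(targets) == 0) next
    new_geno <- cohort$geno[row, targets$qtl] + targets$direction
    if (any(new_geno < 0L | new_geno > 2L)) {
      abort("edit would move allele count outside 0..2")
    }
    cohort$geno[row, targets$qtl] <- new_geno
    hits <- runif(nrow(targets)) < edit_config$offtarget_probability
    cohort$penalty[row] <- cohort$penalty[row] +
      sum(hits) * edit_config$offtarget_effect
    logs[[k]] <- tibble::tibble(animal = cohort$id[row],
                                qtl = targets$qtl,
                                direction = targets$direction,
                                offtarget = hits)
  }
  list(cohort = cohort, edit_log = dplyr::bind_rows(logs))
}
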