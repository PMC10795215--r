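#' Animal cohort
#'
#' A cohort is one discrete generation of a breeding line: per-animal QTL
#' genotypes (allele counts 0/1/2; the neutral SNPs carry no effect and are
#' not tracked per animal), the correlated polygenic breeding values, the
#' heritable off-target health penalty, sex, pedigree links and inbreeding.
#'
#' @param geno `n x n_qtl` integer matrix of allele counts.
#' @param poly `n x 3` matrix of polygenic breeding values (egg, meat,
#'   health).
#' @param sex Character vector (`"M"`/`"F"`).
#' @param generation Integer generation number.
#' @param id Animal ids; `sire`, `dam` parent ids (`NA` for base animals).
#' @param inbreeding Per-animal inbreeding coefficient `F`.
#' @param penalty Accumulated off-target penalty, subtracted from the health
#'   polygenic value.
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(geno, poly, sex, generation, id,
                       sire = rep(NA_integer_, nrow(geno)),
                       dam = rep(NA_integer_, nrow(geno)),
                       inbreeding = rep(0, nrow(geno)),
                       penalty = rep(0, nrow(geno))) {
  stopifnot(nrow(geno) == nrow(poly), length(sex) == nrow(geno),
            all(geno %in% 0:2))
  colnames(poly) <- TRAITS
  structure(list(geno = geno, poly = poly, sex = sex,
                 generation = as.integer(generation),
                 id = as.integer(id), sire = as.integer(sire),
                 dam = as.integer(dam),
                 inbreeding = inbreeding, penalty = penalty),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> generation %d: %d animals (%d M / %d F), %d QTL\n",
              x$generation, nrow(x$geno), sum(x$sex == "M"),
              sum(x$sex == "F"), ncol(x$geno)))
  invisible(x)
}

# Alternating M/F so a 50/50 split holds for any even n.
base_sexes <- function(n) rep(c("M", "F"), length.out = n)

#' Sample a base population from a line state
#'
#' Genotypes are drawn per QTL from Hardy-Weinberg proportions at the line's
#' generation-0 frequencies.  Polygenic breeding values are trivariate normal
#' with cross-trait correlation matrix `Sigma` and per-trait variance reduced
#' from the founder value in proportion to the line's QTL-variance loss (see
#' [polygenic_variance_gen0()]).
#'
#' @param line A `line_state` at generation 0.
#' @param n Number of animals (even; the sex split is 50/50).
#' @param effects A `qtl_effects` object.
#' @param config An [arch_config()].
#' @return A `cohort` of generation 0.
#' @export
sample_base_population <- function(line, n = 500, effects, config = arch_config()) {
  stopifnot(n %% 2 == 0)
  p <- line$qtl_freq
  geno <- matrix(rbinom(n * length(p), 2L, rep(p, each = n)), n)
  v_poly <- polygenic_variance_gen0(line, effects, config)
  poly <- sweep(rmvn(n, chol(config$effect_correlations)), 2, sqrt(v_poly), `*`)
  new_cohort(geno, poly, base_sexes(n), 0L, seq_len(n))
}

#' Build the F1 layer x broiler synthetic base population
#'
#' Each animal draws one allele per QTL from the layer generation-0 frequency
#' and one from the broiler frequency.  Polygenic values are sampled at the
#' mean of the two lines' generation-0 polygenic variances.  The returned
#' `line` element is the synthetic line's own state: reference frequencies
#' `(p_layer + p_broiler)/2` for centering QTL breeding values, and trait
#' means equal to the average of the two line means.
#'
#' @param layer,broiler `line_state`s at generation 0.
#' @param n Number of animals (even).
#' @param effects A `qtl_effects` object.
#' @param config An [arch_config()].
#' @return List with elements `cohort` and `line` (a `line_state` for the
#'   cross).
#' @export
make_cross_base <- function(layer, broiler, n = 500, effects, config = arch_config()) {
  stopifnot(n %% 2 == 0)
  pl <- layer$qtl_freq
  pb <- broiler$qtl_freq
  nq <- length(pl)
  geno <- matrix(rbinom(n * nq, 1L, rep(pl, each = n)) +
                   rbinom(n * nq, 1L, rep(pb, each = n)), n)
  v_poly <- (polygenic_variance_gen0(layer, effects, config) +
               polygenic_variance_gen0(broiler, effects, config)) / 2
  poly <- sweep(rmvn(n, chol(config$effect_correlations)), 2, sqrt(v_poly), `*`)
  cross <- structure(list(
    line_id = "cross",
    frequencies = (layer$frequencies + broiler$frequencies) / 2,
    qtl_freq = (pl + pb) / 2,
    reference_frequencies = (pl + pb) / 2,
    trait_means = (layer$trait_means + broiler$trait_means) / 2
  ), class = "line_state")
  list(cohort = new_cohort(geno, poly, base_sexes(n), 0L, seq_len(n)),
       line = cross)
}

#' QTL part of the true breeding values
#'
#' `TBV_qtl = sum_q (x_q - 2 p_0q) a_qk`, centered at the line's frozen
#' generation-0 reference frequencies.
#'
#' @param cohort A `cohort` (or a bare genotype matrix).
#' @param effects A `qtl_effects` object.
#' @param reference_frequencies The line's generation-0 QTL frequencies.
#' @return `n x 3` matrix of QTL breeding values.
#' @export
tbv_qtl <- function(cohort, effects, reference_frequencies) {
  geno <- if (inherits(cohort, "cohort")) cohort$geno else cohort
  stopifnot(ncol(geno) == length(reference_frequencies))
  centered <- sweep(geno, 2, 2 * reference_frequencies)
  out <- centered %*% effects$a
  colnames(out) <- TRAITS
  out
}

#' Total true breeding values
#'
#' QTL part plus polygenic part, with the accumulated off-target penalty
#' subtracted from the health component.
#'
#' @inheritParams tbv_qtl
#' @return `n x 3` matrix of total breeding values.
#' @export
tbv_total <- function(cohort, effects, reference_frequencies) {
  tbv <- tbv_qtl(cohort, effects, reference_frequencies) + cohort$poly
  tbv[, "health"] <- tbv[, "health"] - cohort$penalty
  tbv
}

#' Breed an offspring cohort
#'
#' For each mating pair, every (unlinked) QTL transmits one allele per parent
#' (homozygotes transmit their allele, heterozygotes a fair coin).  The
#' polygenic value is the parent average plus a Mendelian sampling term with
#' cross-trait correlation `Sigma` and per-trait variance
#' `(1 - F_sire) V_poly / 4 + (1 - F_dam) V_poly / 4`, where `V_poly` is the
#' line's generation-0 polygenic variance.  The off-target penalty is
#' inherited as the parent average.  Sexes fill a fixed 50/50 split in
#' random order.
#'
#' @param parents The parent `cohort`.
#' @param matings Tibble with columns `sire` and `dam` (row indices into
#'   `parents`), one row per offspring.
#' @param v_poly Per-trait polygenic variance of the line at generation 0.
#' @param config An [arch_config()].
#' @param kinship Kinship matrix of the parent cohort (used for the
#'   offspring's inbreeding `F = phi(sire, dam)`).
#' @param id_start First id assigned to the new cohort.
#' @return A `cohort` of generation `parents$generation + 1`.
#' @export
breed_offspring <- function(parents, matings, v_poly, config, kinship,
                            id_start = 1L) {
  s <- matings$sire
  d <- matings$dam
  bad <- c(s, d) < 1 | c(s, d) > nrow(parents$geno)
  if (any(is.na(c(s, d))) || any(bad)) abort("unknown parent in mating list")
  n <- length(s)
  nq <- ncol(parents$geno)
  gamete <- function(idx) {
    g <- parents$geno[idx, , drop = FALSE]
    (g == 2L) + (g == 1L) * (matrix(runif(n * nq), n, nq) < 0.5)
  }
  geno <- gamete(s) + gamete(d)
  storage.mode(geno) <- "integer"
  f_s <- parents$inbreeding[s]
  f_d <- parents$inbreeding[d]
  mend_scale <- sqrt((1 - f_s) / 4 + (1 - f_d) / 4)
  mt <- sweep(rmvn(n, chol(config$effect_correlations)), 2, sqrt(v_poly), `*`) *
    mend_scale
  poly <- (parents$poly[s, , drop = FALSE] + parents$poly[d, , drop = FALSE]) / 2 + mt
  new_cohort(
    geno, poly,
    sex = sample(rep(c("M", "F"), length.out = n)),
    generation = parents$generation + 1L,
    id = seq.int(id_start, length.out = n),
    sire = parents$id[s], dam = parents$id[d],
    inbreeding = kinship[cbind(s, d)],
    penalty = (parents$penalty[s] + parents$penalty[d]) / 2
  )
}

#' Pedigree kinship by the tabular method
#'
#' Computes the kinship (coancestry) matrix `phi` and per-animal inbreeding
#' coefficients from an ordered pedigree: `phi(i, j) = (phi(s_i, j) +
#' phi(d_i, j)) / 2` for `i > j`, `phi(i, i) = (1 + F_i) / 2` with
#' `F_i = phi(s_i, d_i)`.  Founders (missing parents) are unrelated and
#' non-inbred.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam` (parents `NA`
#'   for founders), ordered so parents precede offspring.
#' @param subset Optional ids for which to return the kinship matrix.
#' @return List with `kinship` (matrix over `subset`, default all ids) and
#'   `inbreeding` (named vector over all ids).
#' @export
kinship_tabular <- function(pedigree, subset = pedigree$id) {
  id <- pedigree$id
  n <- length(id)
  pos <- match(pedigree$id, id)
  sp <- match(pedigree$sire, id)
  dp <- match(pedigree$dam, id)
  if (any(!is.na(sp) & sp >= pos) || any(!is.na(dp) & dp >= pos)) {
    abort("pedigree not sorted: parents must precede offspring")
  }
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- sp[i]; di <- dp[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      row <- (`if`(is.na(si), 0, K[si, j]) + `if`(is.na(di), 0, K[di, j])) / 2
      K[i, j] <- row
      K[j, i] <- row
    }
    f <- if (is.na(si) || is.na(di)) 0 else K[si, di]
    K[i, i] <- (1 + f) / 2
  }
  dimnames(K) <- list(id, id)
  fvec <- 2 * diag(K) - 1
  names(fvec) <- id
  idx <- match(subset, id)
  list(kinship = K[idx, idx, drop = FALSE], inbreeding = fvec)
}

#' One-generation kinship recursion for discrete generations
#'
#' With non-overlapping generations, the kinship matrix of an offspring
#' cohort depends only on the parents' kinship matrix:
#' `phi(o, o') = (phi(s_o, s_o') + phi(s_o, d_o') + phi(d_o, s_o') +
#' phi(d_o, d_o')) / 4` for distinct offspring, and
#' `phi(o, o) = (1 + phi(s_o, d_o)) / 2`.  Equivalent to (and tested
#' against) the full tabular method, but O(n^2) per generation.
#'
#' @param kinship Parent-cohort kinship matrix.
#' @param sire,dam Row indices of each offspring's parents.
#' @return Offspring-cohort kinship matrix.
#' @export
update_kinship <- function(kinship, sire, dam) {
  half <- 0.5 * (kinship[sire, , drop = FALSE] + kinship[dam, , drop = FALSE])
  K <- 0.5 * (half[, sire, drop = FALSE] + half[, dam, drop = FALSE])
  diag(K) <- 0.5 * (1 + kinship[cbind(sire, dam)])
  K
}

#' Cohort as a tidy pedigree table
#'
#' @param x A `cohort`.
#' @param ... Unused.
#' @return Tibble with id, sire, dam, sex, generation, inbreeding and
#'   penalty columns.
#' @export
tidy.cohort <- function(x, ...) {
  tibble::tibble(
    id = x$id, sire = x$sire, dam = x$dam, sex = x$sex,
    generation = x$generation, inbreeding = x$inbreeding,
    penalty = x$penalty
  )
}
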