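test_that("base population genotypes follow Hardy-Weinberg at line frequencies", {
  cfg <- arch_config(n_snps = 3, n_qtl = 3, threshold_draws = 1e3)
  e <- fake_effects(matrix(0.01, 3, 3))
  line <- fake_line(c(0.5, 0.2, 0.9))
  set.seed(1)
  coh <- sample_base_population(line, n = 10000, e, cfg)
  counts <- table(factor(coh$geno[, 1], levels = 0:2)) / 10000
  for (k in 0:2) {
    expected <- dbinom(k, 2, 0.5)
    expect_lt(abs(counts[[k + 1]] - expected),
              3 * sqrt(expected * (1 - expected) / 10000))
  }
  expect_lt(abs(mean(coh$geno[, 2]) / 2 - 0.2), 3 * sqrt(0.2 * 0.8 / 20000))
  # centered polygenic values, 50/50 sexes, founders non-inbred
  expect_lt(abs(mean(coh$poly[, "egg"])),
            3 * sqrt(cfg$polygenic_variances[["egg"]] / 10000))
  expect_equal(sum(coh$sex == "M"), 5000)
  expect_true(all(coh$inbreeding == 0))
})

test_that("F1 cross is heterozygous at oppositely fixed QTL and intermediate elsewhere", {
  cfg <- arch_config(n_snps = 2, n_qtl = 2, threshold_draws = 1e3)
  e <- fake_effects(matrix(0.01, 2, 3))
  layer <- fake_line(c(1, 0.8), trait_means = c(egg = 10, meat = 0, health = 0))
  broiler <- fake_line(c(0, 0.2), trait_means = c(egg = 0, meat = 10, health = 0))
  set.seed(2)
  cross <- make_cross_base(layer, broiler, n = 10000, e, cfg)
  expect_true(all(cross$cohort$geno[, 1] == 1L))
  expect_lt(abs(mean(cross$cohort$geno[, 2]) / 2 - 0.5),
            3 * sqrt(0.25 / 20000))
  expect_equal(unname(cross$line$reference_frequencies), c(0.5, 0.5))
  expect_equal(cross$line$trait_means[["egg"]], 5)
})

test_that("the intermated synthetic line has more additive variance than either pure line", {
  # The F1 itself is all-heterozygous at oppositely fixed QTL, so its
  # realized variance is the average of the two lines'; the surplus
  # variance appears once the cross segregates (HWE at the mean
  # frequencies), which is the state compared here.
  cfg <- tiny_arch()
  res <- sapply(1:5, function(r) {
    set.seed(100 + r)
    g <- sample_founder_frequencies(cfg)
    e <- sample_qtl_effects(g, cfg)
    ls <- run_divergent_selection(g, e, cfg)
    va_of <- function(coh, line) {
      apply(tbv_total(coh, e, line$reference_frequencies), 2, var)
    }
    va_l <- va_of(sample_base_population(ls$layer, 400, e, cfg), ls$layer)
    va_b <- va_of(sample_base_population(ls$broiler, 400, e, cfg), ls$broiler)
    cross <- make_cross_base(ls$layer, ls$broiler, 400, e, cfg)
    synthetic <- cross$cohort  # same polygenic values, segregating QTL
    p_bar <- cross$line$qtl_freq
    synthetic$geno <- matrix(rbinom(400 * length(p_bar), 2L,
                                    rep(p_bar, each = 400)), 400)
    va_x <- va_of(synthetic, cross$line)
    va_x - pmax(va_l, va_b)
  })
  expect_true(all(rowMeans(res) > 0))
})

test_that("QTL breeding values are centered substitutions", {
  a <- rbind(c(0.1, -0.05, 0))
  e <- fake_effects(a)
  geno <- matrix(c(2L, 1L, 0L), 3, 1)
  tb <- tbv_qtl(geno, e, reference_frequencies = 0.5)
  expect_equal(unname(tb[1, ]), c(0.1, -0.05, 0))
  expect_equal(unname(tb[2, ]), c(0, 0, 0))   # x = 2 p0 exactly
  expect_equal(unname(tb[3, ]), c(-0.1, 0.05, 0))
  # population mean ~ 0 under HWE at the reference frequencies
  cfg <- arch_config(n_snps = 50, n_qtl = 50, threshold_draws = 1e3)
  e2 <- fake_effects(matrix(rnorm(150, sd = 0.05), 50))
  line <- fake_line(runif(50, 0.05, 0.95))
  set.seed(3)
  coh <- sample_base_population(line, 5000, e2, cfg)
  expect_lt(max(abs(colMeans(tbv_qtl(coh, e2, line$qtl_freq)))), 0.02)
})

test_that("off-target penalty reduces only the health component", {
  e <- fake_effects(matrix(0, 2, 3))
  coh <- new_cohort(matrix(1L, 2, 2), matrix(0, 2, 3), c("M", "F"), 0L, 1:2,
                    penalty = c(0.05, 0))
  tb <- tbv_total(coh, e, c(0.25, 0.25))
  expect_equal(tb[, "health"], c(-0.05, 0) + tbv_qtl(coh, e, c(0.25, 0.25))[, "health"])
  expect_equal(tb[, "egg"], tbv_qtl(coh, e, c(0.25, 0.25))[, "egg"])
})

test_that("inheritance transmits alleles, penalties and Mendelian variance", {
  cfg <- arch_config(n_snps = 2, n_qtl = 2, threshold_draws = 1e3)
  # parents: sire homozygous 0 at QTL1, het at QTL2; dam het / hom-2
  parents <- new_cohort(rbind(c(0L, 1L), c(1L, 2L)),
                        matrix(c(1, 2, 1, 2, 1, 2), 2), c("M", "F"), 0L, 1:2,
                        penalty = c(0.1, 0))
  K <- diag(0.5, 2)
  set.seed(4)
  mat <- tibble::tibble(sire = rep(1L, 10000), dam = rep(2L, 10000))
  v_poly <- c(egg = 0.13, meat = 0.13, health = 0.06)
  off <- breed_offspring(parents, mat, v_poly, cfg, K)
  # QTL1: sire gives 0, dam a fair coin -> frequency 0.25
  expect_lt(abs(mean(off$geno[, 1]) / 2 - 0.25), 3 * sqrt(0.25 * 0.75 / 20000))
  # polygenic: parent average 1.5 per trait + MT with variance V/2 (F = 0)
  expect_lt(abs(mean(off$poly[, "egg"]) - 1.5), 0.02)
  expect_lt(abs(var(off$poly[, "egg"]) - 0.13 / 2), 3 * (0.13 / 2) * sqrt(2 / 10000))
  # penalty inherited as the parent average; F of offspring = phi(s, d) = 0
  expect_true(all(off$penalty == 0.05))
  expect_true(all(off$inbreeding == 0))
  expect_error(breed_offspring(parents, tibble::tibble(sire = 9L, dam = 2L),
                               v_poly, cfg, K), "unknown parent")
})

test_that("tabular kinship reproduces textbook path-counting values", {
  ped <- tibble::tibble(id = 1:5,
                        sire = c(NA, NA, 1L, 1L, 3L),
                        dam = c(NA, NA, 2L, 2L, 4L))
  k <- kinship_tabular(ped)
  expect_equal(k$kinship[1, 2], 0)            # unrelated founders
  expect_equal(k$kinship[1, 1], 0.5)          # non-inbred self-kinship
  expect_equal(k$kinship[3, 4], 0.25)         # full sibs
  expect_equal(unname(k$inbreeding[5]), 0.25) # full-sib mating
  expect_equal(k$kinship[5, 5], (1 + 0.25) / 2)
  expect_error(kinship_tabular(tibble::tibble(id = 1:2, sire = c(2L, NA),
                                              dam = c(NA, NA))), "sorted")
})

test_that("kinship matrices are symmetric PSD and the generation recursion matches", {
  for (seed in c(11, 12)) {
    set.seed(seed)
    n <- 20
    ped <- tibble::tibble(id = 1:n, sire = NA_integer_, dam = NA_integer_)
    K_rec <- diag(0.5, n)
    gens <- list(1:n)
    for (g in 1:3) {
      ids <- max(ped$id) + 1:n
      s <- sample(gens[[g]][1:(n / 2)], n, replace = TRUE)
      d <- sample(gens[[g]][(n / 2 + 1):n], n, replace = TRUE)
      ped <- dplyr::bind_rows(ped, tibble::tibble(id = ids, sire = s, dam = d))
      K_rec <- update_kinship(K_rec, match(s, gens[[g]]), match(d, gens[[g]]))
      gens[[g + 1]] <- ids
    }
    full <- kinship_tabular(ped, subset = gens[[4]])
    expect_equal(unname(full$kinship), unname(K_rec), tolerance = 1e-12)
    expect_equal(K_rec, t(K_rec))
    expect_gte(min(eigen(K_rec, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})
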