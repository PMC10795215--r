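test_that("suggestive effects add the stated one-time noise", {
  cfg <- arch_config()
  n <- 2e4
  e <- fake_effects(matrix(0, n, 3))
  ecfg <- editing_config()
  set.seed(1)
  sugg <- make_suggestive_effects(e, cfg, ecfg)
  v_target <- 0.002 * (cfg$qtl_variances + cfg$polygenic_variances)
  v_emp <- apply(sugg - e$a, 2, var)
  expect_true(all(abs(v_emp / v_target - 1) < 0.05))
  # zero noise reproduces the true effects exactly
  expect_equal(make_suggestive_effects(e, cfg, editing_config(suggestive_noise = 0)),
               e$a)
})

test_that("single-generation estimates have the stated sampling variance", {
  n <- 2e4
  a_sugg <- matrix(0, n, 3)
  set.seed(2)
  est <- generation_estimate(a_sugg, rep(0.5, n), n_animals = 10000)
  # sd = sqrt(1 / (2 * 0.25 * 1e4)) = 0.01414 per trait
  expect_lt(abs(sd(est[, 1]) / 0.014142 - 1), 0.03)
  # low-MAF QTL are inestimable
  est2 <- generation_estimate(matrix(0, 2, 3), c(0.04, 0.5), 1000)
  expect_true(all(is.na(est2[1, ])))
  expect_true(all(!is.na(est2[2, ])))
  # consistency: a huge cohort pins the estimate at the suggestive effect
  est3 <- generation_estimate(matrix(0, 100, 3), rep(0.5, 100), 1e8)
  expect_lt(max(abs(est3)), 1e-3)
  expect_error(generation_estimate(a_sugg, rep(0.5, n), 0), "n_animals")
})

test_that("pooled estimates are cohort-weighted means with shrinking variance", {
  one <- matrix(0.1, 1, 3)
  expect_equal(pooled_estimate(list(one), 5000), one)
  expect_equal(pooled_estimate(list(matrix(0.1, 1, 1), matrix(0.2, 1, 1)),
                               c(10000, 2000)),
               matrix(0.35 / 3, 1, 1), tolerance = 1e-12)
  expect_error(pooled_estimate(list(), 10), "no mapping")
  # pooled sampling variance ~ V_P / (2 p q sum(N))
  n <- 2e4
  set.seed(3)
  ests <- lapply(c(10000, 2000, 2000), function(N) {
    generation_estimate(matrix(0, n, 3), rep(0.5, n), N)
  })
  pooled <- pooled_estimate(ests, c(10000, 2000, 2000))
  v_target <- 1 / (2 * 0.25 * 14000)
  expect_lt(abs(var(pooled[, 2]) / v_target - 1), 0.05)
})

test_that("edit targets are ranked by estimated index effect with skips", {
  w <- line_weights("dual")
  set.seed(4)
  pooled <- matrix(rnorm(60, sd = 0.05), 20, 3)
  pooled[3, ] <- NA  # inestimable
  geno <- rep(1L, 20)
  score <- drop(pooled %*% w)
  tgt <- select_edit_targets(geno, pooled, w, n_edits = 5)
  # brute-force oracle: sort estimable QTL by |score|
  oracle <- order(abs(score), decreasing = TRUE, na.last = NA)[1:5]
  expect_equal(tgt$qtl, oracle)
  expect_equal(tgt$direction, ifelse(score[oracle] >= 0, 1L, -1L))

  # homozygous-beneficial animals skip to the next-best SNP
  ord <- order(abs(score), decreasing = TRUE, na.last = NA)
  geno2 <- geno
  geno2[ord[1]] <- if (score[ord[1]] >= 0) 2L else 0L
  tgt2 <- select_edit_targets(geno2, pooled, w, n_edits = 1)
  expect_equal(tgt2$qtl, ord[2])

  # a single nonzero estimate dominates the ranking
  pooled3 <- matrix(0, 20, 3)
  pooled3[7, ] <- c(0.1, 0, 0)
  expect_equal(select_edit_targets(geno, pooled3, w, n_edits = 1)$qtl, 7L)
})

test_that("edits move allele counts and draw Bernoulli off-target penalties", {
  n_males <- 5000
  geno <- matrix(1L, n_males, 2)
  coh <- new_cohort(geno, matrix(0, n_males, 3), rep("M", n_males), 1L,
                    seq_len(n_males))
  study <- list(pooled = rbind(c(0.2, 0, 0), c(-0.1, 0, 0)))
  ecfg <- editing_config(n_edits = 2)
  set.seed(5)
  out <- apply_edits(coh, seq_len(n_males), study, line_weights("dual"), ecfg)
  # every male edited at both QTL, toward the estimated-beneficial allele
  expect_true(all(out$cohort$geno[, 1] == 2L))
  expect_true(all(out$cohort$geno[, 2] == 0L))
  expect_equal(nrow(out$edit_log), 2 * n_males)
  # off-target incidence ~ 1% of edits, each hit exactly 0.05
  frac <- mean(out$edit_log$offtarget)
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / (2 * n_males)))
  expect_true(all(out$cohort$penalty %in% c(0, 0.05, 0.1)))
  expect_equal(sum(out$cohort$penalty) / 0.05, sum(out$edit_log$offtarget))
})

test_that("a zero edit budget leaves the cohort untouched", {
  coh <- new_cohort(matrix(1L, 3, 2), matrix(0, 3, 3), rep("M", 3), 1L, 1:3)
  study <- list(pooled = rbind(c(0.2, 0, 0), c(-0.1, 0, 0)))
  out <- apply_edits(coh, 1:3, study, line_weights("dual"),
                     editing_config(n_edits = 0))
  expect_identical(out$cohort, coh)
  expect_equal(nrow(out$edit_log), 0)
})
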