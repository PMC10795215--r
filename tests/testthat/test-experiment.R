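test_that("a zero-generation run returns base-population summaries only", {
  cfg <- tiny_scenario(n_generations = 0)
  sim <- run_replicate(cfg, 1)
  expect_equal(nrow(sim$trajectory), 1)
  expect_equal(sim$trajectory$generation, 0L)
  expect_equal(nrow(sim$pedigree), cfg$n_animals)
  expect_true(is.na(sim$trajectory$delta_f))
})

test_that("replicates are bit-reproducible under a fixed seed", {
  cfg <- tiny_scenario(n_edits = 5)
  s1 <- run_replicate(cfg, 99)
  s2 <- run_replicate(cfg, 99)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$edit_log, s2$edit_log)
})

test_that("a zero edit budget makes the editing machinery fully inert", {
  # with n_edits = 0 no mapping-study or off-target randomness may be
  # consumed, so trajectories are identical whatever the other editing
  # parameters say
  cfg_a <- tiny_scenario(n_edits = 0)
  cfg_b <- tiny_scenario(n_edits = 0,
                         editing = editing_config(offtarget_probability = 1,
                                                  suggestive_noise = 0.5))
  s_a <- run_replicate(cfg_a, 7)
  s_b <- run_replicate(cfg_b, 7)
  expect_identical(s_a$trajectory, s_b$trajectory)
  expect_equal(nrow(s_a$edit_log), 0)
})

test_that("gain ratios follow their definition", {
  fake_traj <- function(g0, g20) {
    tibble::tibble(replicate = 1L, generation = c(0L, 20L),
                   tgv_index = c(g0, g20))
  }
  expect_equal(summarize_gain_ratio(fake_traj(0, 10), fake_traj(0, 10)), 0)
  expect_equal(summarize_gain_ratio(fake_traj(0, 10), fake_traj(0, 15)), 50)
  expect_error(summarize_gain_ratio(fake_traj(0, 0), fake_traj(0, 15)),
               "zero")
  expect_error(summarize_gain_ratio(fake_traj(0, 10), fake_traj(0, 15),
                                    horizon = 7), "horizon")
})

test_that("tidy, glance and autoplot expose the trajectories", {
  cfg <- tiny_scenario(n_generations = 2)
  exp2 <- run_scenario(scenario_config("L-Pure", n_edits = 0,
                                       n_generations = 2, n_replicates = 2,
                                       n_animals = 60, arch = tiny_arch(),
                                       seed = 5))
  tr <- tidy(exp2)
  expect_s3_class(tr, "tbl_df")
  expect_equal(nrow(tr), 2 * 3)
  expect_setequal(unique(tr$replicate), 1:2)
  gl <- glance(exp2)
  expect_equal(gl$n_replicates, 2L)
  expect_s3_class(autoplot(exp2), "ggplot")
  expect_s3_class(autoplot(exp2$replicates[[1]], what = "index"), "ggplot")
  expect_s3_class(plot_variance_decay(base = exp2, trait = "meat"), "ggplot")
})

test_that("reports are written and the manifest round-trips byte-identically", {
  out <- withr::local_tempdir()
  cfg <- scenario_config("L-B-cross", n_edits = 5, n_generations = 2,
                         n_replicates = 2, n_animals = 60,
                         arch = tiny_arch(), seed = 31)
  exp1 <- run_scenario(cfg)
  files <- emit_reports(exp1, out)
  expect_true(all(file.exists(file.path(out, c("trajectories.csv",
                                               "checkpoints.csv",
                                               "pedigrees.csv",
                                               "contributions.csv",
                                               "edits.csv",
                                               "manifest.json")))))
  contrib <- readr::read_csv(file.path(out, "contributions.csv"),
                             show_col_types = FALSE)
  # male contributions sum to one half per generation and replicate
  sums <- dplyr::summarise(dplyr::group_by(contrib, replicate, generation),
                           s = sum(contribution), .groups = "drop")
  expect_true(all(abs(sums$s - 0.5) < 1e-6))
  chk <- readr::read_csv(file.path(out, "checkpoints.csv"),
                         show_col_types = FALSE)
  # only generations 1 and (nothing beyond 2) qualify as checkpoints here
  expect_equal(chk$generation, 1)
  expect_equal(chk$n_edits[1], 5)
  exp2 <- run_manifest(file.path(out, "manifest.json"))
  expect_identical(tidy(exp2), tidy(exp1))
})

test_that("an empty trajectory set yields header-only reports", {
  out <- withr::local_tempdir()
  cfg <- scenario_config("L-Pure", n_generations = 0, n_replicates = 1,
                         n_animals = 60, arch = tiny_arch(), seed = 3)
  exp0 <- run_scenario(cfg)
  emit_reports(exp0, out)
  chk <- readr::read_csv(file.path(out, "checkpoints.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(chk), 0)
  expect_true(all(c("tgv_index", "generation") %in% names(chk)))
})
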