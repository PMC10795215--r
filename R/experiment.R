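#' Scenario configuration
#'
#' A scenario is one breeding program: the scheme (dual-purpose line started
#' from the pure layer base, `"L-Pure"`, or from the F1 layer x broiler
#' synthetic, `"L-B-cross"`), the per-male edit budget, horizon, replicate
#' count and master seed.
#'
#' @param scheme `"L-Pure"` or `"L-B-cross"`.
#' @param n_edits SNPs edited per edited male (0 = genomic selection only).
#' @param n_generations Breeding generations after generation 0.
#' @param n_replicates Replicates of the full program.
#' @param n_animals Animals per generation (even; 50/50 sexes).
#' @param weights Selection-index weights of the dual-purpose goal
#'   (override for sensitivity analyses, e.g. `c(0.35, 0.35, 0.30)`).
#' @param ne Effective population size maintained by OCS.
#' @param arch An [arch_config()].
#' @param history A [history_config()].
#' @param editing An [editing_config()]; its `n_edits` is overridden by
#'   `n_edits`.
#' @param seed Master seed; replicate seeds are derived from it.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scheme = c("L-Pure", "L-B-cross"),
                            n_edits = 0,
                            n_generations = 40,
                            n_replicates = 100,
                            n_animals = 500,
                            weights = line_weights("dual"),
                            ne = 100,
                            arch = arch_config(),
                            history = history_config(),
                            editing = editing_config(),
                            seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(n_generations >= 0, n_replicates >= 1, n_animals >= 4,
            n_animals %% 2 == 0)
  editing$n_edits <- as.integer(n_edits)
  structure(list(scheme = scheme, n_edits = as.integer(n_edits),
                 n_generations = as.integer(n_generations),
                 n_replicates = as.integer(n_replicates),
                 n_animals = as.integer(n_animals),
                 weights = setNames(as.numeric(weights), TRAITS),
                 ne = ne, arch = arch, history = history, editing = editing,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

cohort_fixed_qtl <- function(geno) {
  cs <- colSums(geno)
  sum(cs == 0L | cs == 2L * nrow(geno))
}

trajectory_row <- function(cohort, effects, line, weights, kinship) {
  tbv <- tbv_total(cohort, effects, line$reference_frequencies)
  tgv <- colMeans(tbv) + line$trait_means
  va <- apply(tbv, 2, var)
  tibble::tibble(
    generation = cohort$generation,
    tgv_egg = tgv[["egg"]], tgv_meat = tgv[["meat"]],
    tgv_health = tgv[["health"]],
    tgv_index = sum(weights * tgv),
    va_egg = va[["egg"]], va_meat = va[["meat"]], va_health = va[["health"]],
    poly_health = mean(cohort$poly[, "health"] - cohort$penalty),
    n_fixed_qtl = cohort_fixed_qtl(cohort$geno),
    mean_kinship = mean(kinship),
    mean_inbreeding = mean(cohort$inbreeding)
  )
}

#' Run one replicate of a breeding program
#'
#' Executes the full pipeline: architecture sampling, analytic 100-generation
#' divergence, base population (pure layer or F1 cross), then per breeding
#' generation EBV simulation, optimum contribution selection of sires,
#' optional gene editing of the top sires (from generation 1), random mating
#' with equal dam contributions, Mendelian inheritance and the reliability
#' update.  Two stream seeds are derived from `replicate_seed`: one for
#' architecture + history, one for the breeding phase, so paired scenario
#' arms (same `replicate_seed`, different edit budget) share their founders.
#'
#' @param config A [scenario_config()].
#' @param replicate_seed Integer seed of this replicate.
#' @return An object of class `ge_sim`: `trajectory` (tibble with one row
#'   per generation 0..n), `pedigree`, `edit_log`, `contributions` (the
#'   per-generation OCS solution: male id, index EBV, contribution),
#'   `line_means`, `config`, `replicate_seed`.
#' @export
run_replicate <- function(config, replicate_seed) {
  seeds <- derive_seeds(replicate_seed, 2)
  arch <- config$arch

  set.seed(seeds[1])
  genome <- sample_founder_frequencies(arch)
  effects <- sample_qtl_effects(genome, arch)
  lines <- run_divergent_selection(genome, effects, arch, config$history)

  set.seed(seeds[2])
  if (config$scheme == "L-Pure") {
    line <- lines$layer
    cohort <- sample_base_population(line, config$n_animals, effects, arch)
    v_poly0 <- polygenic_variance_gen0(line, effects, arch)
  } else {
    base <- make_cross_base(lines$layer, lines$broiler, config$n_animals,
                            effects, arch)
    line <- base$line
    cohort <- base$cohort
    v_poly0 <- (polygenic_variance_gen0(lines$layer, effects, arch) +
                  polygenic_variance_gen0(lines$broiler, effects, arch)) / 2
  }
  kinship <- diag(0.5, config$n_animals)
  r2 <- initial_reliability()
  editing <- config$editing
  study <- if (config$n_edits > 0) {
    new_mapping_study(effects, lines$layer, lines$broiler, arch, editing)
  }

  traj <- vector("list", config$n_generations + 1L)
  ped <- vector("list", config$n_generations + 1L)
  logs <- list()
  contribs <- vector("list", config$n_generations)
  next_id <- config$n_animals + 1L
  lambda_hint <- NULL

  for (t in seq_len(config$n_generations)) {
    tbv <- tbv_total(cohort, effects, line$reference_frequencies)
    v_a <- pmax(apply(tbv, 2, var), 0)
    ebv <- simulate_ebv(tbv, r2, v_a)
    u <- index_value(ebv, config$weights)
    male_idx <- which(cohort$sex == "M")
    female_idx <- which(cohort$sex == "F")
    ocs <- optimum_contributions(u[male_idx], kinship, male_idx, female_idx,
                                 ne = config$ne, lambda_init = lambda_hint)
    lambda_hint <- ocs$lambda
    contribs[[t]] <- tibble::tibble(generation = cohort$generation,
                                    male_id = cohort$id[male_idx],
                                    ebv_index = u[male_idx],
                                    contribution = ocs$contributions)

    if (config$n_edits > 0 && cohort$generation >= 1) {
      study <- advance_mapping_study(study, editing)
      rank <- order(-ocs$contributions, -u[male_idx], male_idx)
      top <- male_idx[rank][seq_len(min(editing$n_edited_males,
                                        length(male_idx)))]
      edited <- apply_edits(cohort, top, study, config$weights, editing)
      cohort <- edited$cohort
      if (nrow(edited$edit_log) > 0) {
        logs[[length(logs) + 1L]] <-
          dplyr::mutate(edited$edit_log, generation = cohort$generation)
      }
    }

    traj[[t]] <- trajectory_row(cohort, effects, line, config$weights, kinship)
    ped[[t]] <- generics::tidy(cohort)

    matings <- allocate_matings(ocs$contributions, male_idx, female_idx,
                                config$n_animals)
    offspring <- breed_offspring(cohort, matings, v_poly0, arch, kinship,
                                 id_start = next_id)
    next_id <- next_id + config$n_animals
    kinship <- update_kinship(kinship, matings$sire, matings$dam)
    r2 <- update_reliability(r2)
    cohort <- offspring
  }
  traj[[config$n_generations + 1L]] <-
    trajectory_row(cohort, effects, line, config$weights, kinship)
  ped[[config$n_generations + 1L]] <- generics::tidy(cohort)

  trajectory <- dplyr::bind_rows(traj)
  trajectory$delta_f <- c(NA_real_,
                          diff(trajectory$mean_kinship) /
                            (1 - head(trajectory$mean_kinship, -1)))
  structure(list(trajectory = trajectory,
                 pedigree = dplyr::bind_rows(ped),
                 edit_log = dplyr::bind_rows(logs),
                 contributions = dplyr::bind_rows(contribs),
                 line_means = line$trait_means,
                 config = config,
                 replicate_seed = replicate_seed),
            class = "ge_sim")
}

#' @export
print.ge_sim <- function(x, ...) {
  cat(sprintf("<ge_sim> %s, %d edits/male, %d generations (seed %d)\n",
              x$config$scheme, x$config$n_edits, x$config$n_generations,
              x$replicate_seed))
  print(x$trajectory, n = 5)
  invisible(x)
}

#' @export
tidy.ge_sim <- function(x, ...) x$trajectory

#' @export
glance.ge_sim <- function(x, ...) {
  tr <- x$trajectory
  tibble::tibble(
    scheme = x$config$scheme,
    n_edits = x$config$n_edits,
    n_generations = x$config$n_generations,
    index_gain = tr$tgv_index[nrow(tr)] - tr$tgv_index[1],
    mean_delta_f = mean(tr$delta_f, na.rm = TRUE),
    final_inbreeding = tr$mean_inbreeding[nrow(tr)]
  )
}

#' Run all replicates of a scenario
#'
#' @param config A [scenario_config()].
#' @param replicate_seeds Optional explicit per-replicate seeds (used to pair
#'   arms across scenarios); default derived from `config$seed`.
#' @param progress Emit a message per replicate.
#' @return An object of class `ge_experiment` (list of `ge_sim` replicates).
#' @export
run_scenario <- function(config, replicate_seeds = NULL, progress = FALSE) {
  if (is.null(replicate_seeds)) {
    replicate_seeds <- derive_seeds(config$seed, config$n_replicates)
  }
  sims <- purrr::imap(replicate_seeds, function(s, i) {
    if (progress) message(sprintf("replicate %d/%d", i, length(replicate_seeds)))
    run_replicate(config, s)
  })
  structure(list(replicates = sims, config = config), class = "ge_experiment")
}

#' @export
print.ge_experiment <- function(x, ...) {
  cat(sprintf("<ge_experiment> %s, %d edits/male: %d replicates x %d generations\n",
              x$config$scheme, x$config$n_edits, length(x$replicates),
              x$config$n_generations))
  invisible(x)
}

#' @export
tidy.ge_experiment <- function(x, ...) {
  purrr::imap(x$replicates, function(s, i) {
    dplyr::mutate(s$trajectory, replicate = i, .before = 1)
  }) |> dplyr::bind_rows()
}

#' @export
glance.ge_experiment <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$replicates, generics::glance)) |>
    dplyr::summarise(
      scheme = dplyr::first(.data$scheme),
      n_edits = dplyr::first(.data$n_edits),
      n_replicates = dplyr::n(),
      mean_index_gain = mean(.data$index_gain),
      sd_index_gain = sd(.data$index_gain),
      mean_delta_f = mean(.data$mean_delta_f)
    )
}

index_gain_per_replicate <- function(x, horizon) {
  tr <- if (inherits(x, "ge_experiment")) generics::tidy(x) else x
  stopifnot(all(c("replicate", "generation", "tgv_index") %in% names(tr)))
  if (!horizon %in% tr$generation) abort("horizon not present in trajectories")
  tr |>
    dplyr::filter(.data$generation %in% c(0, horizon)) |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(gain = .data$tgv_index[.data$generation == horizon] -
                       .data$tgv_index[.data$generation == 0],
                     .groups = "drop")
}

#' Percent extra genetic gain from editing
#'
#' `100 (G_edit - G_base) / G_base`, where `G` is the mean dual-purpose
#' index gain from generation 0 to the horizon over replicates.  Baseline
#' and edited arms are normally paired (same founder seeds).
#'
#' @param baseline,edited `ge_experiment` objects (or their [generics::tidy()]
#'   tibbles) for the no-editing and editing arms.
#' @param horizon Generation at which gains are compared.
#' @return Percent extra gain (scalar).
#' @export
summarize_gain_ratio <- function(baseline, edited, horizon = 20) {
  gb <- mean(index_gain_per_replicate(baseline, horizon)$gain)
  ge <- mean(index_gain_per_replicate(edited, horizon)$gain)
  if (abs(gb) < .Machine$double.eps^0.5) {
    abort("baseline gain is zero; gain ratio undefined")
  }
  100 * (ge - gb) / gb
}

#' Write scenario reports
#'
#' Writes the per-generation trajectories, a checkpoint table of TGV changes
#' at generations 1/10/20/40 (those present), the pedigrees, the
#' per-generation OCS contribution and edit logs, and a JSON manifest of
#' the configuration and seeds that reproduces the run.  All tables are
#' delimited text with a `replicate` column.
#'
#' @param experiment A `ge_experiment`.
#' @param out_dir Output directory (created if missing).
#' @param checkpoints Generations summarised in the checkpoint table.
#' @return Paths of the written files, invisibly.
#' @export
emit_reports <- function(experiment, out_dir,
                         checkpoints = c(1, 10, 20, 40)) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  tr <- generics::tidy(experiment)
  f_traj <- file.path(out_dir, "trajectories.csv")
  readr::write_csv(tr, f_traj)

  per_rep <- function(field) {
    purrr::imap(experiment$replicates, function(s, i) {
      dplyr::mutate(s[[field]], replicate = i, .before = 1)
    }) |> dplyr::bind_rows()
  }
  f_ped <- file.path(out_dir, "pedigrees.csv")
  readr::write_csv(per_rep("pedigree"), f_ped)
  f_con <- file.path(out_dir, "contributions.csv")
  readr::write_csv(per_rep("contributions"), f_con)
  f_edit <- file.path(out_dir, "edits.csv")
  readr::write_csv(per_rep("edit_log"), f_edit)

  chk <- tr |>
    dplyr::filter(.data$generation %in% checkpoints) |>
    dplyr::group_by(.data$generation) |>
    dplyr::summarise(dplyr::across(
      c("tgv_egg", "tgv_meat", "tgv_health", "tgv_index"), mean),
      .groups = "drop") |>
    dplyr::mutate(scheme = experiment$config$scheme,
                  n_edits = experiment$config$n_edits, .before = 1)
  f_chk <- file.path(out_dir, "checkpoints.csv")
  readr::write_csv(chk, f_chk)

  cfg <- experiment$config
  manifest <- list(scheme = cfg$scheme, n_edits = cfg$n_edits,
                   n_generations = cfg$n_generations,
                   n_replicates = length(experiment$replicates),
                   n_animals = cfg$n_animals,
                   weights = unname(cfg$weights), ne = cfg$ne,
                   seed = cfg$seed,
                   n_snps = cfg$arch$n_snps, n_qtl = cfg$arch$n_qtl,
                   threshold_draws = cfg$arch$threshold_draws,
                   threshold_seed = cfg$arch$threshold_seed)
  f_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA)
  invisible(c(f_traj, f_chk, f_ped, f_con, f_edit, f_man))
}

#' Re-run a scenario from a manifest
#'
#' @param path Path to a `manifest.json` written by [emit_reports()].
#' @return A `ge_experiment`.
#' @export
run_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- scenario_config(
    scheme = m$scheme, n_edits = m$n_edits,
    n_generations = m$n_generations, n_replicates = m$n_replicates,
    n_animals = m$n_animals, weights = m$weights, ne = m$ne,
    arch = arch_config(n_snps = m$n_snps, n_qtl = m$n_qtl,
                       threshold_draws = m$threshold_draws,
                       threshold_seed = m$threshold_seed),
    seed = m$seed
  )
  run_scenario(cfg)
}
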