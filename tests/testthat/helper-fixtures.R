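# Small architectures keep unit tests fast; the acceptance suite uses the
# full-size defaults.
tiny_arch <- function(...) {
  arch_config(n_snps = 300, n_qtl = 40, threshold_draws = 2e4,
              threshold_seed = 11L, ...)
}

tiny_scenario <- function(scheme = "L-Pure", n_edits = 0, n_generations = 3,
                          n_animals = 60, ...) {
  scenario_config(scheme, n_edits = n_edits, n_generations = n_generations,
                  n_replicates = 1, n_animals = n_animals,
                  arch = tiny_arch(), ...)
}

# Hand-built qtl_effects object for oracle tests.
fake_effects <- function(a, founder_freq = rep(0.5, nrow(a))) {
  colnames(a) <- c("egg", "meat", "health")
  structure(list(a = a, tau2 = rep(1, nrow(a)), founder_freq = founder_freq,
                 threshold = 0, scaling = rep(1, 3)),
            class = "qtl_effects")
}

fake_line <- function(qtl_freq, trait_means = c(egg = 0, meat = 0, health = 0),
                      id = "toy") {
  structure(list(line_id = id, frequencies = qtl_freq, qtl_freq = qtl_freq,
                 reference_frequencies = qtl_freq, trait_means = trait_means),
            class = "line_state")
}

# Random positive-definite kinship-like matrix with base-animal diagonal.
random_kinship <- function(n, seed) {
  withr::with_seed(seed, {
    A <- matrix(runif(n * n, 0, 0.2), n)
    K <- 0.1 * crossprod(A) / n + diag(0.3, n)
    (K + t(K)) / 2
  })
}
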