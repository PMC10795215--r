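Package: dualGE
Title: Stochastic Simulation of Dual-Purpose Chicken Breeding with
    Genomic Selection and Gene Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates closed poultry breeding programs that develop a
    dual-purpose chicken line (selected simultaneously for egg production,
    meat production and overall health) by genomic selection, with or
    without gene editing of the top sires.  Trait architecture is built
    from 500 pleiotropic QTL with effects drawn from a truncated
    multivariate t distribution plus a correlated polygenic remainder.
    Generation-0 layer and broiler lines are derived analytically from 100
    generations of divergent index truncation selection.  Breeding uses
    simulated genomic EBVs with a reliability recursion and optimum
    contribution selection of sires under a pedigree coancestry-rate
    constraint (effective population size 100).  Gene editing promotes the
    estimated-beneficial alleles of the largest-effect SNPs in the top 25
    sires, with a heritable off-target penalty on polygenic health.
    Results are tidy per-generation trajectories of true genetic values,
    additive variances and inbreeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
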