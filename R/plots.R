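#' Plot genetic-gain trajectories
#'
#' Replicate-mean true genetic values (per trait or the dual-purpose index)
#' against generation, one line per trait.
#'
#' @param object A `ge_sim` or `ge_experiment`.
#' @param what `"traits"` for the three traits, `"index"` for the
#'   dual-purpose index.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ge_experiment <- function(object, what = c("traits", "index"), ...) {
  what <- match.arg(what)
  tr <- generics::tidy(object)
  if (what == "index") {
    dat <- tr |>
      dplyr::group_by(.data$generation) |>
      dplyr::summarise(value = mean(.data$tgv_index), .groups = "drop")
    return(ggplot2::ggplot(dat, ggplot2::aes(.data$generation, .data$value)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "Generation", y = "Dual-purpose index TGV"))
  }
  dat <- tr |>
    dplyr::group_by(.data$generation) |>
    dplyr::summarise(dplyr::across(c("tgv_egg", "tgv_meat", "tgv_health"),
                                   mean), .groups = "drop") |>
    tidyr::pivot_longer(-"generation", names_to = "trait",
                        names_prefix = "tgv_", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(.data$generation, .data$value,
                                    colour = .data$trait)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "Mean TGV (founder SD units)",
                  colour = "Trait")
}

#' @rdname autoplot.ge_experiment
#' @export
autoplot.ge_sim <- function(object, what = c("traits", "index"), ...) {
  fake <- structure(list(replicates = list(object), config = object$config),
                    class = "ge_experiment")
  autoplot.ge_experiment(fake, what = what, ...)
}

#' Compare additive-variance erosion across scenario arms
#'
#' @param ... Named `ge_experiment` objects (names label the arms).
#' @param trait One of `"egg"`, `"meat"`, `"health"`.
#' @return A ggplot object.
#' @export
plot_variance_decay <- function(..., trait = c("egg", "meat", "health")) {
  trait <- match.arg(trait)
  arms <- list(...)
  col <- paste0("va_", trait)
  dat <- purrr::imap(arms, function(x, nm) {
    generics::tidy(x) |>
      dplyr::group_by(.data$generation) |>
      dplyr::summarise(value = mean(.data[[col]]), .groups = "drop") |>
      dplyr::mutate(arm = nm)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(dat, ggplot2::aes(.data$generation, .data$value,
                                    colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation",
                  y = sprintf("Additive variance (%s)", trait),
                  colour = NULL)
}
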