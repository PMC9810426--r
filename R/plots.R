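#' Plot a spatial state-probability map
#'
#' Tile map of the grid: observed populations show their state, inference
#' targets their posterior probability of state 1.
#'
#' @param map Output of [state_map()].
#' @return A ggplot object.
#' @export
plot_state_map <- function(map) {
  stopifnot(all(c("row", "col", "p_state_1") %in% names(map)))
  ggplot2::ggplot(map, ggplot2::aes(x = .data$col, y = .data$row,
                                    fill = .data$p_state_1)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$status == "observed", as.character(.data$state),
                     ifelse(.data$status == "infer", "?", ""))),
      size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "#d95f02", high = "#1f78b4",
                                 limits = c(0, 1), na.value = "grey90",
                                 name = "P(state 1)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Trace and density plots for a sampler run
#'
#' @param object A `"cultree_mcmc"` object.
#' @param parameters Draw columns to show (default: the free model
#'   parameters and the TMRCA).
#' @param ... Unused.
#' @return A ggplot object (facetted traces with marginal densities).
#' @export
autoplot.cultree_mcmc <- function(object, parameters = NULL, ...) {
  if (is.null(parameters))
    parameters <- c(free_param_names(object), "tmrca")
  df <- object$draws[, c("iteration", parameters)]
  long <- tidyr::pivot_longer(df, -"iteration", names_to = "parameter",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, color = "#1f78b4") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a genealogy
#'
#' @param object A [genealogy()].
#' @param ... Passed to [ape::plot.phylo()].
#' @return Invisibly, the ape phylo used for plotting.
#' @export
autoplot.genealogy <- function(object, ...) {
  phy <- as_phylo(object)
  ape::plot.phylo(phy, ...)
  invisible(phy)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
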