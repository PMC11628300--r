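#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map of pixel trend labels
#'
#' @param labels Tibble with `row`, `col`, `label`.
#' @return A ggplot.
#' @export
plot_trend_map <- function(labels) {
  ggplot2::ggplot(labels, ggplot2::aes(.data$col, .data$row,
                                       fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = -1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "trend",
                  title = "Nonlinear trend classes of the carbon sink") +
    ggplot2::theme_minimal()
}

#' Map of stability classes
#'
#' @param stability Tibble with `row`, `col`, `stability_class`.
#' @return A ggplot.
#' @export
plot_stability_map <- function(stability) {
  ggplot2::ggplot(stability,
                  ggplot2::aes(.data$col, .data$row,
                               fill = factor(.data$stability_class))) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1,
                               na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "class (1 = stable)",
                  title = "Detrended-CV stability classes") +
    ggplot2::theme_minimal()
}

#' Relative influence of the drivers, optionally per stratum
#'
#' @param influence Tibble `driver`, `influence`, `group` and optionally
#'   `stratum` (from [relative_influence()] or
#'   [stratified_attribution()]`$influence`).
#' @return A ggplot.
#' @export
plot_influence <- function(influence) {
  p <- ggplot2::ggplot(influence,
                       ggplot2::aes(stats::reorder(.data$driver,
                                                   .data$influence),
                                    .data$influence, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "relative influence (%)", fill = NULL,
                  title = "Driver attribution of carbon-sink stability") +
    ggplot2::theme_minimal()
  if ("stratum" %in% names(influence)) {
    p <- p + ggplot2::facet_wrap(~stratum)
  }
  p
}

#' Deviance trace of a boosted-tree fit
#'
#' @param object A `sink_brt`.
#' @param ... Unused.
#' @return A ggplot of training and out-of-bag deviance by iteration.
#' @export
autoplot.sink_brt <- function(object, ...) {
  tibble::tibble(iteration = seq_len(object$n_trees),
                 train = object$train_deviance,
                 out_of_bag = object$oob_deviance) |>
    tidyr::pivot_longer(-"iteration", names_to = "set",
                        values_to = "deviance") |>
    ggplot2::ggplot(ggplot2::aes(.data$iteration, .data$deviance,
                                 colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Boosting deviance trace") +
    ggplot2::theme_minimal()
}

#' Scenario class shares by overlap stratum
#'
#' @param comparison Output of [compare_scenarios()].
#' @return A ggplot.
#' @export
plot_scenario_shares <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(factor(.data$stratum), .data$share,
                               fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_grid(type ~ scenario) +
    ggplot2::labs(x = "overlap stratum", y = "share (%)", fill = NULL,
                  title = "Projected trend and stability class shares") +
    ggplot2::theme_minimal()
}
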