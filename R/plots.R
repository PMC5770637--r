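# ggplot2 views of the result tables.

#' Plot recovery trajectories per compartment
#'
#' Temporal trajectories of tracer recovery (% of the applied dose) with
#' mean +/- SE ribbons where standard errors are available.
#'
#' @param table A recovery table (`compartment, year, recovery_mean`,
#'   optionally `recovery_se`).
#' @return A ggplot object.
#' @export
plot_recovery_trajectories <- function(table) {
  stopifnot(all(c("compartment", "year", "recovery_mean") %in% names(table)))
  p <- ggplot2::ggplot(table,
                       ggplot2::aes(x = .data$year, y = .data$recovery_mean,
                                    colour = .data$compartment))
  if ("recovery_se" %in% names(table)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$recovery_mean - .data$recovery_se,
                   ymax = .data$recovery_mean + .data$recovery_se,
                   fill = .data$compartment),
      alpha = 0.15, colour = NA)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "year", y = "15N recovery [% of applied]",
                  colour = "compartment", fill = "compartment") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flow_ledger <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(edge = paste(.data$from, "→", .data$to))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$edge,
                                                     .data$flow),
                                  y = .data$flow, fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "flow [% of applied tracer]",
                  title = "Inferred between-compartment tracer flows") +
    ggplot2::theme_minimal()
}
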