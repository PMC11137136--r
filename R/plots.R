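#' Fitness-versus-rank curve for a ranked screen table
#'
#' Plots the number of models reaching each fitness score or higher - the
#' standard view for choosing a percentile cutoff: a steep initial drop
#' (strong candidates) followed by a near-linear tail.
#'
#' @param object A `screen_table` from [rank_models()].
#' @param top_fraction Optional fraction marked with a vertical cutoff line
#'   (e.g. 0.025); `NULL` for none.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_table
#' @export
autoplot.screen_table <- function(object, top_fraction = NULL, ...) {
  curve <- fitness_rank_curve(object)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_models, y = .data$fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "number of models at or above fitness",
      y = "fitness (%)",
      title = "Model fitness by rank"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(top_fraction)) {
    p <- p + ggplot2::geom_vline(
      xintercept = ceiling(top_fraction * nrow(curve)),
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}

#' Distribution of best delays in a ranked table
#'
#' @param table A `screen_table` with a `delay_min` column.
#' @return A ggplot bar chart of the count of models per best delay.
#' @export
plot_delay_distribution <- function(table) {
  tb <- tibble::as_tibble(table)
  ggplot2::ggplot(tb, ggplot2::aes(x = factor(.data$delay_min))) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "best delay (min)", y = "models",
                  title = "Best-delay distribution") +
    ggplot2::theme_minimal()
}
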