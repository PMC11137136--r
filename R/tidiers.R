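#' Tidy a pairwise fit into a one-row tibble
#'
#' @param x A `pairwise_fit` from [fit_pairwise()] or [fit_delay_scan()].
#' @param ... Unused.
#' @return A one-row tibble with the fit record used throughout the screen:
#'   `input_id`, `output_id`, `donor_id`, `delay_min`, `alpha`, `beta`,
#'   `gamma`, `sign`, `fitness`, `n_fit_points`, `degenerate`.
#' @method tidy pairwise_fit
#' @export
tidy.pairwise_fit <- function(x, ...) {
  tibble::tibble(
    input_id = x$input_id,
    output_id = x$output_id,
    donor_id = x$donor_id,
    delay_min = x$delay_min,
    alpha = x$alpha,
    beta = x$beta,
    gamma = x$gamma,
    sign = x$sign,
    fitness = x$fitness,
    n_fit_points = x$n_fit_points,
    degenerate = x$degenerate
  )
}

#' One-line model summary for a pairwise fit
#'
#' @param x A `pairwise_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `fitness`, `delay_min`, `sign`,
#'   `continuous_a` (per-minute self-regulation rate, `log(alpha)/step`)
#'   and `degenerate`.
#' @method glance pairwise_fit
#' @export
glance.pairwise_fit <- function(x, ...) {
  tibble::tibble(
    fitness = x$fitness,
    delay_min = x$delay_min,
    sign = x$sign,
    continuous_a = continuous_a(x$alpha, x$step_min),
    degenerate = x$degenerate
  )
}

#' Plot observed vs free-run simulated output for one fit
#'
#' @param object A `pairwise_fit`.
#' @param ... Unused.
#' @return A ggplot of the observed target trajectory and the model's
#'   free-run reproduction over the usable (delay-truncated) window.
#' @method autoplot pairwise_fit
#' @export
autoplot.pairwise_fit <- function(object, ...) {
  idx <- seq_along(object$observed) + object$time_offset - 1L
  df <- tibble::tibble(
    time_min = rep(idx * object$step_min, 2L),
    value = c(object$observed, object$simulated),
    series = rep(c("observed", "simulated"), each = length(idx))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "time (min)", y = "intensity (a.u.)", colour = NULL,
      title = sprintf("%s -> %s: fitness %.2f%%, delay %g min",
                      object$input_id, object$output_id,
                      object$fitness, object$delay_min)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom generics glance
#' @export
generics::glance

#' @export
generics::tidy

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
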