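#' Uniform sampling grid for expression time series
#'
#' All series handled by the package share one clock: `n_points` samples
#' taken every `step_min` minutes starting at `start_min`. The default is
#' the design used throughout the package's reference workflow: 19 points
#' at 20-minute intervals, i.e. six hours of sampling.
#'
#' @param n_points Number of timepoints (at least 3).
#' @param step_min Sampling interval in minutes (positive).
#' @param start_min Time of the first sample in minutes.
#'
#' @return An object of class `time_grid`: a list with fields `start_min`,
#'   `step_min` and `n_points`.
#' @examples
#' grid <- time_grid()
#' grid_times(grid) # 0, 20, ..., 360 minutes
#' @export
time_grid <- function(n_points = 19L, step_min = 20, start_min = 0) {
  stopifnot_scalar_number(step_min, "step_min", positive = TRUE)
  stopifnot_scalar_number(start_min, "start_min")
  stopifnot_scalar_number(n_points, "n_points")
  n_points <- as.integer(n_points)
  if (n_points < 3L) {
    rlang::abort("`n_points` must be at least 3.")
  }
  structure(
    list(start_min = start_min, step_min = step_min, n_points = n_points),
    class = "time_grid"
  )
}

#' @rdname time_grid
#' @param grid A `time_grid`.
#' @return `grid_times()` returns the numeric vector of sampling times in
#'   minutes.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$start_min + grid$step_min * (seq_len(grid$n_points) - 1L)
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf(
    "<time_grid> %d points every %g min, %g-%g min\n",
    x$n_points, x$step_min, x$start_min,
    x$start_min + x$step_min * (x$n_points - 1L)
  ))
  invisible(x)
}

# Convert a delay grid given in minutes into integer step counts on `grid`.
# Delays must be nonnegative multiples of the sampling interval.
delay_min_to_steps <- function(delay_min, grid) {
  stopifnot(inherits(grid, "time_grid"))
  if (length(delay_min) == 0L) {
    rlang::abort("Delay grid must be nonempty.")
  }
  steps <- delay_min / grid$step_min
  bad <- delay_min < 0 | abs(steps - round(steps)) > 1e-8
  if (any(bad)) {
    rlang::abort(sprintf(
      "Delays must be nonnegative multiples of the sampling interval (%g min); offending: %s",
      grid$step_min, paste(delay_min[bad], collapse = ", ")
    ))
  }
  as.integer(round(steps))
}
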