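#' Delay a candidate-regulator series by whole sampling steps
#'
#' Shifting the input right by `d` steps aligns output index `k` with input
#' index `k - d`. No padding is invented: the usable fitting window is the
#' part of the output series for which the delayed input exists, so a
#' 19-point series fitted at delay 5 leaves a 14-point window.
#'
#' @param u Numeric input series.
#' @param d Nonnegative integer delay in sampling steps; must satisfy
#'   `d < length(u) - 2` so that a nontrivial window remains.
#' @return The delayed input values aligned to output indices
#'   `(d + 1):length(u)`, i.e. `u[1:(length(u) - d)]`.
#' @examples
#' shift_input(c(1, 2, 3, 4), 1) # 1 2 3 -> used for outputs 2..4
#' @export
shift_input <- function(u, d) {
  if (!is.numeric(u) || length(u) < 3L) {
    rlang::abort("`u` must be a numeric series of length >= 3.")
  }
  d <- check_delay_steps(d, length(u))
  u[seq_len(length(u) - d)]
}

check_delay_steps <- function(d, n) {
  stopifnot_scalar_number(d, "d")
  if (abs(d - round(d)) > 1e-8 || d < 0) {
    rlang::abort("`d` must be a nonnegative integer number of steps.")
  }
  d <- as.integer(round(d))
  if (d >= n - 2L) {
    rlang::abort(sprintf(
      "Delay of %d steps leaves no usable window for a series of length %d.", d, n
    ))
  }
  d
}

#' Normalized root-mean-square fitness of a simulated trajectory
#'
#' The score is `100 * (1 - ||y - yhat|| / ||y - mean(y)||)` (Euclidean
#' norms): 100 for a perfect reproduction of the observed series, 0 for a
#' model no better than the constant mean predictor, and negative - never
#' clamped - when the model is worse than the mean. A constant observed
#' series has no deviation to explain and yields `NaN` with a warning.
#'
#' @param y Observed output series.
#' @param yhat Simulated output series of the same length.
#' @return Fitness in percent (scalar); at most 100, with equality iff
#'   `yhat` equals `y`.
#' @examples
#' fitness_score(c(1, 2, 3), c(1, 2, 4)) # 100 * (1 - 1/sqrt(2))
#' @export
fitness_score <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    rlang::abort("`y` and `yhat` must have equal length.")
  }
  if (!all(is.finite(y)) || !all(is.finite(yhat))) {
    rlang::abort("Series must be finite.")
  }
  denom <- sqrt(sum((y - mean(y))^2))
  if (denom == 0) {
    rlang::warn("Observed series is constant; fitness is undefined.")
    return(NaN)
  }
  100 * (1 - sqrt(sum((y - yhat)^2)) / denom)
}

#' Free-run simulation of a fitted pairwise model
#'
#' Recursion `yhat[k + 1] = alpha * yhat[k] + beta * u[k - d] + gamma`,
#' anchored at `yhat = y0` at the first usable index (`d + 1`) and never
#' re-anchored to the observed data afterwards.
#'
#' @param u Input series over the full grid.
#' @param alpha,beta,gamma Discrete model parameters.
#' @param d Delay in steps.
#' @param y0 Initial value at the first usable index.
#' @return Simulated series over the usable window, length `length(u) - d`.
#' @examples
#' simulate_pairwise(c(2, 2, 2), alpha = 0.5, beta = 1, gamma = 0,
#'                   d = 0, y0 = 0) # 0 2 3
#' @export
simulate_pairwise <- function(u, alpha, beta, gamma, d = 0L, y0) {
  d <- check_delay_steps(d, length(u))
  n <- length(u)
  len <- n - d
  yhat <- numeric(len)
  yhat[1L] <- y0
  if (len > 1L) {
    for (j in seq_len(len - 1L)) {
      yhat[j + 1L] <- alpha * yhat[j] + beta * u[j] + gamma
    }
  }
  yhat
}

# Centered one-step-ahead OLS for y[k+1] = alpha y[k] + beta u[k-d] + gamma.
# Shared by the single-pair and the vectorized genome-scale paths.
# Returns list(alpha, beta, gamma, degenerate).
ols_core <- function(y_now, u_lag, y_next) {
  m <- length(y_next)
  ybar <- mean(y_now); ubar <- mean(u_lag); nbar <- mean(y_next)
  yc <- y_now - ybar; uc <- u_lag - ubar; nc <- y_next - nbar
  syy <- sum(yc * yc); suu <- sum(uc * uc); suy <- sum(uc * yc)
  syn <- sum(yc * nc); sun <- sum(uc * nc)
  det <- syy * suu - suy * suy
  if (syy <= 0 || suu <= 0 || det <= .Machine$double.eps * syy * suu * 1e4) {
    return(list(alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                degenerate = TRUE))
  }
  alpha <- (syn * suu - sun * suy) / det
  beta <- (sun * syy - syn * suy) / det
  gamma <- nbar - alpha * ybar - beta * ubar
  list(alpha = alpha, beta = beta, gamma = gamma, degenerate = FALSE)
}

sign_label <- function(beta) {
  dplyr::case_when(
    is.na(beta) ~ NA_character_,
    beta > 0 ~ "activator",
    beta < 0 ~ "repressor",
    TRUE ~ NA_character_ # beta exactly 0: no regulation either way
  )
}

#' Fit one delayed first-order model to a regulator/target pair
#'
#' Estimates the discrete-time model
#' `y[k + 1] = alpha * y[k] + beta * u[k - d] + gamma`
#' by ordinary least squares on the one-step-ahead prediction error (the
#' exact minimizer of the prediction-error criterion for this model class),
#' then scores the fit by free-run simulation ([simulate_pairwise()]) with
#' [fitness_score()]. The sign of `beta` classifies the candidate as an
#' activator (positive) or repressor (negative); a zero or inestimable gain
#' is flagged degenerate and carries `NaN` fitness.
#'
#' @param pair A data frame with numeric columns `u` (candidate regulator)
#'   and `y` (target), one row per timepoint in grid order.
#' @param d Delay in sampling steps (default 0).
#' @param step_min Sampling interval in minutes, used only to report the
#'   delay in minutes (default 20).
#' @param input_id,output_id,donor_id Optional labels carried into the
#'   result.
#' @return A `pairwise_fit` object; see [tidy.pairwise_fit()] for the
#'   one-row tibble form.
#' @examples
#' grid_t <- seq(0, 360, by = 20)
#' u <- 100 + 50 * sin(grid_t / 60)
#' y <- simulate_pairwise(u, 0.5, 0.3, 10, d = 0, y0 = 20)
#' fit <- fit_pairwise(data.frame(u = u, y = y))
#' fit$fitness # 100: the model class contains the truth
#' @export
fit_pairwise <- function(pair, d = 0L, step_min = 20,
                         input_id = "u", output_id = "y", donor_id = "donor") {
  pair <- check_series_pair(pair)
  n <- nrow(pair)
  d <- check_delay_steps(d, n)
  if (n - d < 4L) {
    rlang::abort("At least 4 usable points are needed to fit 3 parameters.")
  }
  u <- pair$u; y <- pair$y
  k <- (d + 1L):(n - 1L) # output indices with both a successor and a lagged input
  est <- ols_core(y_now = y[k], u_lag = u[k - d], y_next = y[k + 1L])
  window <- (d + 1L):n
  degenerate <- est$degenerate || identical(est$beta, 0)
  if (!est$degenerate && est$beta == 0) degenerate <- TRUE
  if (degenerate) {
    fitness <- NaN
    yhat <- rep(NA_real_, length(window))
  } else {
    yhat <- simulate_pairwise(u, est$alpha, est$beta, est$gamma, d = d,
                              y0 = y[d + 1L])
    fitness <- suppressWarnings(fitness_score(y[window], yhat))
    if (is.nan(fitness)) degenerate <- TRUE # constant observed output
  }
  structure(
    list(
      input_id = input_id, output_id = output_id, donor_id = donor_id,
      alpha = est$alpha, beta = est$beta, gamma = est$gamma,
      delay_steps = d, step_min = step_min, delay_min = d * step_min,
      sign = if (degenerate) NA_character_ else sign_label(est$beta),
      fitness = fitness, n_fit_points = length(window),
      degenerate = degenerate,
      observed = y[window], simulated = yhat, time_offset = d
    ),
    class = "pairwise_fit"
  )
}

check_series_pair <- function(pair) {
  if (!is.data.frame(pair) || !all(c("u", "y") %in% names(pair))) {
    rlang::abort("`pair` must be a data frame with columns `u` and `y`.")
  }
  if (nrow(pair) < 3L) {
    rlang::abort("Series must have at least 3 timepoints.")
  }
  if (!all(is.finite(pair$u)) || !all(is.finite(pair$y))) {
    rlang::abort("Series must be finite.")
  }
  pair
}

#' Fit a pair across a grid of input delays and keep the best
#'
#' Fits [fit_pairwise()] at every delay in `delays` and returns the fit
#' with the highest free-run fitness; exact ties go to the smallest delay
#' (parsimony), and degenerate fits are excluded from the maximization.
#'
#' @inheritParams fit_pairwise
#' @param delays Integer delays in sampling steps (default `0:5`,
#'   i.e. 0-100 minutes at a 20-minute step).
#' @return The best `pairwise_fit`; if every delay is degenerate, the fit at
#'   the smallest delay is returned with its degenerate flag set.
#' @export
fit_delay_scan <- function(pair, delays = 0:5, step_min = 20,
                           input_id = "u", output_id = "y", donor_id = "donor") {
  if (length(delays) == 0L) {
    rlang::abort("`delays` must be nonempty.")
  }
  delays <- sort(unique(as.integer(delays)))
  fits <- purrr::map(delays, function(d) {
    fit_pairwise(pair, d = d, step_min = step_min, input_id = input_id,
                 output_id = output_id, donor_id = donor_id)
  })
  ok <- !purrr::map_lgl(fits, "degenerate")
  if (!any(ok)) {
    return(fits[[1L]])
  }
  fit_vals <- purrr::map_dbl(fits, "fitness")
  fit_vals[!ok] <- -Inf
  best <- which(fit_vals == max(fit_vals))[1L] # delays ascending: ties -> smallest
  fits[[best]]
}

#' @export
print.pairwise_fit <- function(x, ...) {
  cat(sprintf(
    "<pairwise_fit> %s -> %s (%s)\n", x$input_id, x$output_id, x$donor_id
  ))
  if (x$degenerate) {
    cat("  degenerate fit (no usable regulation signal)\n")
  } else {
    cat(sprintf(
      "  delay %g min | fitness %.2f%% | %s\n  alpha %.4g, beta %.4g, gamma %.4g (continuous a = %.4g /min)\n",
      x$delay_min, x$fitness, x$sign, x$alpha, x$beta, x$gamma,
      continuous_a(x$alpha, x$step_min)
    ))
  }
  invisible(x)
}

# Continuous-time self-regulation rate recovered from the discrete
# coefficient: a = ln(alpha)/step for alpha > 0, else NA.
continuous_a <- function(alpha, step_min) {
  ifelse(is.finite(alpha) & alpha > 0, log(alpha) / step_min, NA_real_)
}
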