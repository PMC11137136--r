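#' Configuration of an all-to-one regulator screen
#'
#' @param target_output_ids Character vector of transcript IDs used as the
#'   screen's outputs (the target gene's probesets; typically two).
#' @param delay_grid_min Candidate input delays in minutes; nonnegative
#'   multiples of the sampling interval, sorted ascending. Default
#'   `c(0, 20, 40, 60, 80, 100)`.
#' @param ranking_donor Donor label whose fitness orders the final list.
#'   `NULL` (default) designates the second donor supplied to [all2one()],
#'   the convention when one donor's series are cleaner than the other's.
#' @param top_fraction Fraction of ranked models kept by [top_percentile()]
#'   (default 0.025).
#' @param consistency_mode Only `"per-output-cross-donor"` is implemented:
#'   an input must show the same activator/repressor sign in every donor,
#'   separately for each output transcript.
#' @return A `screen_config` list.
#' @export
screen_config <- function(target_output_ids,
                          delay_grid_min = c(0, 20, 40, 60, 80, 100),
                          ranking_donor = NULL,
                          top_fraction = 0.025,
                          consistency_mode = "per-output-cross-donor") {
  if (length(target_output_ids) < 1L) {
    rlang::abort("At least one target output transcript ID is required.")
  }
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    rlang::abort("`top_fraction` must be in (0, 1].")
  }
  if (is.unsorted(delay_grid_min) || any(delay_grid_min < 0)) {
    rlang::abort("`delay_grid_min` must be nonnegative and sorted ascending.")
  }
  consistency_mode <- match.arg(consistency_mode, "per-output-cross-donor")
  structure(
    list(
      target_output_ids = as.character(target_output_ids),
      delay_grid_min = delay_grid_min,
      ranking_donor = ranking_donor,
      top_fraction = top_fraction,
      consistency_mode = consistency_mode
    ),
    class = "screen_config"
  )
}

# Vectorized one-step OLS + free-run fitness for all candidate inputs at one
# delay. U: inputs x N matrix; y: target series of length N.
fit_bulk_delay <- function(U, y, d) {
  n <- length(y)
  stopifnot(ncol(U) == n, d >= 0, n - d >= 4L)
  k <- (d + 1L):(n - 1L)
  y_now <- y[k]; y_next <- y[k + 1L]
  Ulag <- U[, k - d, drop = FALSE]
  m <- length(k)
  ybar <- mean(y_now); nbar <- mean(y_next)
  yc <- y_now - ybar; nc <- y_next - nbar
  syy <- sum(yc * yc); syn <- sum(yc * nc)
  ubar <- rowMeans(Ulag)
  Uc <- Ulag - ubar
  suu <- rowSums(Uc * Uc)
  suy <- drop(Uc %*% yc)
  sun <- drop(Uc %*% nc)
  det <- syy * suu - suy^2
  degenerate <- syy <= 0 | suu <= 0 |
    det <= .Machine$double.eps * syy * suu * 1e4
  alpha <- (syn * suu - sun * suy) / det
  beta <- (sun * syy - syn * suy) / det
  gamma <- nbar - alpha * ybar - beta * ubar
  degenerate <- degenerate | !is.finite(beta) | beta == 0
  # free-run simulation over the usable window, vectorized across inputs
  len <- n - d
  yw <- y[(d + 1L):n]
  Yhat <- matrix(NA_real_, nrow = nrow(U), ncol = len)
  Yhat[, 1L] <- yw[1L]
  for (j in seq_len(len - 1L)) {
    Yhat[, j + 1L] <- alpha * Yhat[, j] + beta * U[, j] + gamma
  }
  denom <- sqrt(sum((yw - mean(yw))^2))
  fitness <- if (denom == 0) {
    rep(NaN, nrow(U))
  } else {
    resid <- Yhat - matrix(yw, nrow = nrow(U), ncol = len, byrow = TRUE)
    100 * (1 - sqrt(rowSums(resid^2)) / denom)
  }
  degenerate <- degenerate | !is.finite(fitness)
  fitness[degenerate] <- NaN
  tibble::tibble(
    input_id = rownames(U),
    delay_steps = d,
    alpha = unname(alpha), beta = unname(beta), gamma = unname(gamma),
    fitness = unname(fitness),
    n_fit_points = len,
    degenerate = unname(degenerate)
  )
}

# Best-delay fit per input for one (donor, output): scans the delay grid and
# keeps the highest fitness, ties to the smallest delay.
fit_bulk_scan <- function(U, y, delay_steps) {
  per_delay <- lapply(delay_steps, function(d) fit_bulk_delay(U, y, d))
  fitmat <- vapply(per_delay, function(tb) {
    f <- tb$fitness
    f[tb$degenerate] <- -Inf
    f
  }, numeric(nrow(U)))
  fitmat <- matrix(fitmat, nrow = nrow(U))
  best_j <- max.col(fitmat, ties.method = "first") # delays ascending
  all_bad <- !is.finite(apply(fitmat, 1L, max))
  best_j[all_bad] <- 1L
  rows <- purrr::map_dfr(seq_along(delay_steps), function(j) {
    sel <- which(best_j == j)
    per_delay[[j]][sel, , drop = FALSE]
  })
  rows <- rows[order(match(rows$input_id, rownames(U))), , drop = FALSE]
  rows$degenerate <- rows$degenerate | all_bad
  rows$fitness[rows$degenerate] <- NaN
  rows
}

#' Screen every transcript as a candidate regulator of the target outputs
#'
#' Runs the all-to-one sweep: for every donor, every target output and every
#' candidate input transcript, fits the delayed first-order model at each
#' delay in the grid and retains the delay with the highest free-run
#' fitness. Transcripts listed as target outputs are excluded from the
#' candidate inputs.
#'
#' @param datasets List of [expr_dataset()] objects sharing transcript IDs
#'   and row order (see [intersect_donors()]).
#' @param config A [screen_config()].
#' @return A tibble of best-delay fit records, one row per
#'   (input, output, donor): `input_id`, `gene_symbol`, `output_id`,
#'   `donor_id`, `delay_min`, `delay_steps`, `alpha`, `beta`, `gamma`,
#'   `sign`, `fitness`, `n_fit_points`, `degenerate`.
#' @export
all2one <- function(datasets, config) {
  stopifnot(inherits(config, "screen_config"))
  if (inherits(datasets, "expr_dataset")) datasets <- list(datasets)
  ids0 <- datasets[[1L]]$transcript_ids
  for (ds in datasets) {
    if (!identical(ds$transcript_ids, ids0)) {
      rlang::abort("Datasets must share transcript IDs and row order; run intersect_donors() first.")
    }
  }
  missing_targets <- setdiff(config$target_output_ids, ids0)
  if (length(missing_targets) > 0L) {
    rlang::abort(sprintf(
      "Target output transcript(s) not present in the datasets: %s",
      paste(missing_targets, collapse = ", ")
    ))
  }
  grid <- datasets[[1L]]$grid
  delay_steps <- delay_min_to_steps(config$delay_grid_min, grid)
  input_ids <- setdiff(ids0, config$target_output_ids)
  if (length(input_ids) == 0L) {
    rlang::abort("No candidate input transcripts remain after excluding the targets.")
  }
  symbols <- if (is.null(datasets[[1L]]$gene_symbols)) {
    stats::setNames(rep(NA_character_, length(ids0)), ids0)
  } else {
    stats::setNames(datasets[[1L]]$gene_symbols, ids0)
  }
  fits <- purrr::map_dfr(datasets, function(ds) {
    U <- ds$values[input_ids, , drop = FALSE]
    purrr::map_dfr(config$target_output_ids, function(out_id) {
      y <- ds$values[out_id, ]
      best <- fit_bulk_scan(U, y, delay_steps)
      dplyr::mutate(best,
        output_id = out_id,
        donor_id = ds$donor_id,
        delay_min = .data$delay_steps * grid$step_min,
        sign = ifelse(.data$degenerate, NA_character_, sign_label(.data$beta)),
        gene_symbol = unname(symbols[.data$input_id])
      )
    })
  })
  dplyr::select(
    fits,
    "input_id", "gene_symbol", "output_id", "donor_id",
    "delay_min", "delay_steps", "alpha", "beta", "gamma",
    "sign", "fitness", "n_fit_points", "degenerate"
  )
}

#' Discard inputs with inconsistent activator/repressor calls across donors
#'
#' An input transcript survives only if, for every target output, the sign
#' of its input gain agrees across all donors; an input with a degenerate
#' fit for any (donor, output) is discarded as well. All fits of a
#' discarded input are removed.
#'
#' @param fits Fit records from [all2one()].
#' @param config A [screen_config()] (reserved for alternative modes).
#' @return A list with `fits` (the retained records) and `discarded`
#'   (tibble of `input_id` and `reason`).
#' @export
consistency_filter <- function(fits, config = NULL) {
  check_fits(fits)
  status <- fits |>
    dplyr::group_by(.data$input_id, .data$output_id) |>
    dplyr::summarise(
      any_degenerate = any(.data$degenerate),
      consistent = dplyr::n_distinct(.data$sign) == 1L,
      .groups = "drop_last"
    ) |>
    dplyr::summarise(
      any_degenerate = any(.data$any_degenerate),
      consistent = all(.data$consistent),
      .groups = "drop"
    )
  discarded <- status |>
    dplyr::filter(.data$any_degenerate | !.data$consistent) |>
    dplyr::mutate(reason = ifelse(.data$any_degenerate, "degenerate fit",
                                  "sign disagreement across donors")) |>
    dplyr::select("input_id", "reason")
  list(
    fits = dplyr::filter(fits, !.data$input_id %in% discarded$input_id),
    discarded = discarded
  )
}

check_fits <- function(fits) {
  needed <- c("input_id", "output_id", "donor_id", "sign", "fitness", "degenerate")
  if (!is.data.frame(fits) || !all(needed %in% names(fits))) {
    rlang::abort("`fits` must be a fit-record data frame from all2one().")
  }
  invisible(fits)
}

#' Rank the retained models by fitness
#'
#' Orders the (input, output) models of the ranking donor by fitness,
#' descending; exact ties break lexicographically by input then output ID.
#' The fitness each model achieved in every donor is carried along in
#' `fitness_<donor>` columns.
#'
#' @param fits Fit records, normally after [consistency_filter()].
#' @param config A [screen_config()]; its `ranking_donor` (or, when `NULL`,
#'   the second donor present in `fits`) provides the ordering fitness.
#' @return A `screen_table`: a tibble with a leading `rank` column (1 =
#'   highest fitness).
#' @export
rank_models <- function(fits, config) {
  check_fits(fits)
  stopifnot(inherits(config, "screen_config"))
  donors <- unique(fits$donor_id)
  ranking_donor <- config$ranking_donor %||%
    donors[min(2L, length(donors))]
  if (!ranking_donor %in% donors) {
    rlang::abort(sprintf("Ranking donor '%s' has no fits.", ranking_donor))
  }
  donor_fitness <- fits |>
    dplyr::select("input_id", "output_id", "donor_id", "fitness") |>
    tidyr::pivot_wider(names_from = "donor_id", values_from = "fitness",
                       names_prefix = "fitness_")
  table <- fits |>
    dplyr::filter(.data$donor_id == ranking_donor) |>
    dplyr::left_join(donor_fitness, by = c("input_id", "output_id")) |>
    dplyr::arrange(dplyr::desc(.data$fitness), .data$input_id, .data$output_id) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1L)
  new_screen_table(table, ranking_donor = ranking_donor)
}

new_screen_table <- function(x, ranking_donor = attr(x, "ranking_donor")) {
  structure(
    x,
    ranking_donor = ranking_donor,
    class = unique(c("screen_table", class(tibble::as_tibble(x))))
  )
}

#' Keep the top fraction of a ranked table
#'
#' Keeps the first `ceiling(fraction * nrow(table))` rows, so a 7030-model
#' table cut at 2.5 percent keeps 176 models.
#'
#' @param table A `screen_table` from [rank_models()].
#' @param fraction Fraction in (0, 1].
#' @return The truncated `screen_table`.
#' @export
top_percentile <- function(table, fraction = 0.025) {
  if (!(fraction > 0 && fraction <= 1)) {
    rlang::abort("`fraction` must be in (0, 1].")
  }
  keep <- ceiling(fraction * nrow(table))
  new_screen_table(dplyr::slice_head(tibble::as_tibble(table), n = keep),
                   ranking_donor = attr(table, "ranking_donor"))
}

#' Collapse a ranked table to distinct gene identities
#'
#' Rows are grouped by gene symbol; rows without a symbol keep their
#' transcript ID as their own identity (probe-ID rows). Each identity
#' retains its best-ranked row.
#'
#' @param table A `screen_table` (needs `rank` and `input_id`; uses
#'   `gene_symbol` when present).
#' @return A tibble with one row per distinct identity, ordered by rank,
#'   with a leading `identity` column; the number of collapsed duplicate
#'   rows is attached as attribute `n_collapsed`.
#' @export
collapse_to_genes <- function(table) {
  tb <- tibble::as_tibble(table)
  if (!"rank" %in% names(tb)) {
    rlang::abort("`table` must have a `rank` column.")
  }
  if ("gene_name" %in% names(tb)) {
    # published-style table: one name column mixing symbols and probe IDs
    identity <- tb$gene_name
  } else if ("input_id" %in% names(tb)) {
    sym <- if ("gene_symbol" %in% names(tb)) tb$gene_symbol else
      rep(NA_character_, nrow(tb))
    identity <- dplyr::if_else(is.na(sym) | sym == "", tb$input_id, sym)
  } else {
    rlang::abort("`table` must have `gene_name` or `input_id` columns.")
  }
  out <- tb |>
    dplyr::mutate(identity = identity, .before = 1L) |>
    dplyr::group_by(.data$identity) |>
    dplyr::slice_min(.data$rank, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$rank)
  attr(out, "n_collapsed") <- nrow(tb) - nrow(out)
  out
}

#' Post-hoc shortlist filters on a ranked table
#'
#' Optional filters used when narrowing a ranked list to testable
#' candidates: drop rows whose annotation maps to more than one gene
#' (Affymetrix `"///"` convention) and rows whose best delay falls outside
#' a biologically plausible window (default 20-60 minutes, roughly the time
#' to translate a regulator and act on its target's promoter).
#'
#' @param table A `screen_table` with `gene_symbol` and `delay_min`.
#' @param delay_window_min Length-2 numeric window (inclusive) of admissible
#'   delays in minutes; `NULL` disables the delay filter.
#' @param exclude_multi_gene Drop rows annotated to multiple genes.
#' @return The filtered `screen_table`.
#' @export
candidate_filters <- function(table, delay_window_min = c(20, 60),
                              exclude_multi_gene = TRUE) {
  tb <- tibble::as_tibble(table)
  if (exclude_multi_gene && "gene_symbol" %in% names(tb)) {
    tb <- dplyr::filter(
      tb, is.na(.data$gene_symbol) | !grepl("///", .data$gene_symbol, fixed = TRUE)
    )
  }
  if (!is.null(delay_window_min)) {
    if (length(delay_window_min) != 2L) {
      rlang::abort("`delay_window_min` must be a length-2 window or NULL.")
    }
    tb <- dplyr::filter(
      tb,
      .data$delay_min >= delay_window_min[1L],
      .data$delay_min <= delay_window_min[2L]
    )
  }
  new_screen_table(tb, ranking_donor = attr(table, "ranking_donor"))
}

#' @export
print.screen_table <- function(x, ...) {
  rd <- attr(x, "ranking_donor")
  cat(sprintf("<screen_table> %d ranked models%s\n", nrow(x),
              if (is.null(rd)) "" else sprintf(" (ranking donor: %s)", rd)))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
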