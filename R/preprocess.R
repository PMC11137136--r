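#' Detection-call (flag) filter
#'
#' Removes any transcript whose detection call is Absent (`A`) at every
#' timepoint; a transcript is kept as soon as a single call is Present (`P`)
#' or Marginal (`M`). Row order is preserved.
#'
#' @param ds An [expr_dataset()] with a flag matrix. Datasets without flags
#'   are rejected: skipping this filter must be an explicit pipeline choice
#'   (see `use_flag_filter` in [preprocess_datasets()]), never a silent one.
#'
#' @return A list with elements `dataset` (the filtered [expr_dataset()])
#'   and `report` (a one-row tibble: `rule`, `n_input`, `n_kept`,
#'   `removed_ids` list-column).
#' @export
flag_filter <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (is.null(ds$flags)) {
    rlang::abort(paste(
      "Dataset has no detection calls; the flag filter cannot run.",
      "Skip it explicitly with `use_flag_filter = FALSE` if flags are unavailable."
    ))
  }
  keep <- rowSums(ds$flags == "P" | ds$flags == "M") > 0L
  filter_result(ds, keep, rule = "flag")
}

#' Intensity filter
#'
#' Keeps a transcript only if its average intensity over all timepoints is
#' at least `mean_min` and its largest intensity is at least `peak_min`
#' (defaults 50 and 100, in the arbitrary units of the normalized linear
#' scale).
#'
#' @param ds An [expr_dataset()] on the linear scale.
#' @param mean_min Minimum mean intensity (nonnegative).
#' @param peak_min Minimum peak intensity (nonnegative).
#' @return A list with `dataset` and `report`, as in [flag_filter()].
#' @export
intensity_filter <- function(ds, mean_min = 50, peak_min = 100) {
  stopifnot(inherits(ds, "expr_dataset"))
  stopifnot_scalar_number(mean_min, "mean_min")
  stopifnot_scalar_number(peak_min, "peak_min")
  if (mean_min < 0 || peak_min < 0) {
    rlang::abort("Intensity thresholds must be nonnegative.")
  }
  keep <- rowMeans(ds$values) >= mean_min &
    apply(ds$values, 1L, max) >= peak_min
  filter_result(ds, keep, rule = "intensity")
}

filter_result <- function(ds, keep, rule) {
  report <- tibble::tibble(
    donor_id = ds$donor_id,
    rule = rule,
    n_input = length(keep),
    n_kept = sum(keep),
    removed_ids = list(ds$transcript_ids[!keep])
  )
  list(dataset = subset_dataset(ds, ds$transcript_ids[keep]), report = report)
}

#' Restrict donors to their common transcripts
#'
#' Each dataset is restricted to the intersection of all donors' transcript
#' IDs, in identical (lexicographic) row order, so that downstream pairing
#' across donors is positional.
#'
#' @param datasets A list of two or more [expr_dataset()] objects.
#' @return A list of [expr_dataset()] objects of equal shape and row order.
#' @export
intersect_donors <- function(datasets) {
  if (!is.list(datasets) || length(datasets) < 2L ||
      !all(vapply(datasets, inherits, logical(1L), "expr_dataset"))) {
    rlang::abort("`datasets` must be a list of at least two expr_dataset objects.")
  }
  common <- Reduce(intersect, lapply(datasets, function(d) d$transcript_ids))
  if (length(common) == 0L) {
    rlang::abort("No transcripts are shared by all donors (empty intersection).")
  }
  common <- sort(common)
  lapply(datasets, subset_dataset, ids = common)
}

#' Standard preprocessing pipeline for a set of donor datasets
#'
#' Applies, per donor, the detection-call filter (unless explicitly skipped)
#' followed by the intensity filter, then restricts all donors to their
#' common transcript set via [intersect_donors()].
#'
#' @param datasets List of [expr_dataset()] objects (linear scale).
#' @param use_flag_filter Set to `FALSE` to skip the flag filter when no
#'   detection calls exist; never skipped silently.
#' @param mean_min,peak_min Thresholds for [intensity_filter()].
#' @return A list with `datasets` (the filtered, intersected list) and
#'   `report` (tibble of per-donor filter counts plus the final common
#'   count).
#' @export
preprocess_datasets <- function(datasets, use_flag_filter = TRUE,
                                mean_min = 50, peak_min = 100) {
  if (inherits(datasets, "expr_dataset")) datasets <- list(datasets)
  reports <- list()
  filtered <- purrr::map(datasets, function(ds) {
    if (use_flag_filter) {
      ff <- flag_filter(ds)
      reports[[length(reports) + 1L]] <<- ff$report
      ds <- ff$dataset
    }
    inf <- intensity_filter(ds, mean_min = mean_min, peak_min = peak_min)
    reports[[length(reports) + 1L]] <<- inf$report
    inf$dataset
  })
  if (length(filtered) >= 2L) {
    filtered <- intersect_donors(filtered)
  }
  report <- dplyr::bind_rows(reports)
  report <- dplyr::bind_rows(
    report,
    tibble::tibble(
      donor_id = "all",
      rule = "intersection",
      n_input = sum(purrr::map_int(datasets, ~ nrow(.x$values))),
      n_kept = nrow(filtered[[1L]]$values),
      removed_ids = list(character())
    )
  )
  list(datasets = filtered, report = report)
}
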