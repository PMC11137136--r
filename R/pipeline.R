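#' Run the full screening pipeline on in-memory datasets
#'
#' Executes preprocess (optional) -> all-to-one sweep -> cross-donor
#' consistency filter -> ranking -> percentile cut, and assembles a run
#' manifest whose counts reconcile across stages.
#'
#' @param datasets List of [expr_dataset()] objects, one per donor.
#' @param config A [screen_config()].
#' @param preprocess Apply [preprocess_datasets()] first (default `TRUE`).
#' @param use_flag_filter,mean_min,peak_min Passed to
#'   [preprocess_datasets()].
#' @return A list with `table` (the cut `screen_table`), `full_table` (the
#'   complete ranking), `fits` (retained fit records), `manifest` (list of
#'   stage counts and the config snapshot), and `report` (preprocessing
#'   filter report, when preprocessing ran).
#' @export
run_pipeline <- function(datasets, config, preprocess = TRUE,
                         use_flag_filter = TRUE, mean_min = 50, peak_min = 100) {
  stopifnot(inherits(config, "screen_config"))
  if (inherits(datasets, "expr_dataset")) datasets <- list(datasets)
  report <- NULL
  if (preprocess) {
    pp <- stage("preprocess", preprocess_datasets(
      datasets, use_flag_filter = use_flag_filter,
      mean_min = mean_min, peak_min = peak_min
    ))
    datasets <- pp$datasets
    report <- pp$report
  }
  fits <- stage("all2one", all2one(datasets, config))
  cons <- stage("consistency", consistency_filter(fits, config))
  full_table <- stage("rank", rank_models(cons$fits, config))
  table <- stage("cut", top_percentile(full_table, config$top_fraction))
  n_inputs_screened <- length(unique(fits$input_id))
  n_inputs_retained <- length(unique(cons$fits$input_id))
  manifest <- list(
    config = unclass(config),
    ranking_donor = attr(full_table, "ranking_donor"),
    n_donors = length(datasets),
    n_transcripts = nrow(datasets[[1L]]$values),
    n_inputs_screened = n_inputs_screened,
    n_outputs = length(config$target_output_ids),
    n_fits = nrow(fits),
    n_inputs_discarded = nrow(cons$discarded),
    n_inputs_retained = n_inputs_retained,
    n_models_ranked = nrow(full_table),
    n_models_kept = nrow(table),
    version = as.character(utils::packageVersion("regscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  stopifnot(manifest$n_models_ranked ==
              manifest$n_inputs_retained * manifest$n_outputs)
  list(table = table, full_table = full_table, fits = cons$fits,
       discarded = cons$discarded, manifest = manifest, report = report)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), parent = e)
  })
}

#' Run the pipeline from files on disk
#'
#' File-level wrapper around [run_pipeline()]: reads per-donor expression
#' (and optional flag) tables, runs the screen, and writes the ranked
#' table, the fitness-rank curve, the filter report and the JSON manifest
#' into `out_dir`.
#'
#' @param expr_paths Character vector of expression-table paths, one per
#'   donor, in donor order.
#' @param donor_ids Donor labels (default `donor1`, `donor2`, ...).
#' @param config A [screen_config()].
#' @param grid A [time_grid()].
#' @param flag_paths Optional flag-table paths aligned with `expr_paths`.
#' @param delog Back-transform log2 values on read.
#' @param out_dir Output directory; `NULL` skips writing.
#' @inheritParams run_pipeline
#' @return As [run_pipeline()], plus `paths` of written files.
#' @export
run_pipeline_files <- function(expr_paths,
                               donor_ids = sprintf("donor%d", seq_along(expr_paths)),
                               config, grid = time_grid(),
                               flag_paths = NULL, delog = FALSE,
                               out_dir = NULL, use_flag_filter = !is.null(flag_paths),
                               mean_min = 50, peak_min = 100) {
  if (!is.null(flag_paths) && length(flag_paths) != length(expr_paths)) {
    rlang::abort("`flag_paths` must align with `expr_paths`.")
  }
  datasets <- purrr::map(seq_along(expr_paths), function(i) {
    stage("read", read_expression_table(
      expr_paths[i], donor_id = donor_ids[i], grid = grid,
      flags_path = if (is.null(flag_paths)) NULL else flag_paths[i],
      delog = delog
    ))
  })
  res <- run_pipeline(datasets, config, use_flag_filter = use_flag_filter,
                      mean_min = mean_min, peak_min = peak_min)
  if (!is.null(out_dir)) {
    res$paths <- write_screen_outputs(res, out_dir)
  }
  res
}

write_screen_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ranked = file.path(out_dir, "ranked_models.tsv"),
    top = file.path(out_dir, "top_models.tsv"),
    curve = file.path(out_dir, "fitness_rank_curve.tsv"),
    manifest = file.path(out_dir, "run_manifest.json")
  )
  readr::write_tsv(tibble::as_tibble(res$full_table), paths[["ranked"]],
                   progress = FALSE)
  readr::write_tsv(tibble::as_tibble(res$table), paths[["top"]],
                   progress = FALSE)
  readr::write_tsv(fitness_rank_curve(res$full_table), paths[["curve"]],
                   progress = FALSE)
  jsonlite::write_json(res$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(res$report)) {
    paths[["filter_report"]] <- file.path(out_dir, "filter_report.json")
    jsonlite::write_json(
      dplyr::select(res$report, -"removed_ids"),
      paths[["filter_report"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  paths
}

#' Cumulative count of models at or above each fitness level
#'
#' For a ranked table this is simply the pairs (rank, fitness): the number
#' of models reaching a given fitness score or higher, the curve commonly
#' plotted to choose a cutoff on the steep initial drop.
#'
#' @param table A `screen_table`.
#' @return A tibble with `n_models` (cumulative count) and `fitness`,
#'   fitness non-increasing.
#' @export
fitness_rank_curve <- function(table) {
  tb <- tibble::as_tibble(table)
  if (nrow(tb) == 0L) {
    return(tibble::tibble(n_models = integer(), fitness = numeric()))
  }
  tibble::tibble(n_models = seq_len(nrow(tb)), fitness = tb$fitness)
}

#' Published ranked-list fixture
#'
#' Loads the packaged 176-row ranked candidate list (gene or probe-set
#' name, best delay in minutes, fitness in percent) used for report and
#' round-trip tests. The file is checksummed to guard against silent
#' corruption.
#'
#' @return A `screen_table` with columns `rank`, `gene_name`, `delay_min`,
#'   `fitness`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "ranked_candidates_published.tsv",
                      package = "regscreen", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  expected <- "6b38fe94da1223d9eb127ffc043bfcfd"
  if (!identical(md5, expected)) {
    rlang::abort(sprintf(
      "Fixture %s is corrupted (md5 %s, expected %s).", path, md5, expected
    ))
  }
  tb <- readr::read_tsv(path, col_types = "icid", progress = FALSE)
  new_screen_table(tb, ranking_donor = "donor2")
}
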