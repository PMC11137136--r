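#' Per-donor expression dataset
#'
#' An `expr_dataset` bundles one donor's transcript-by-timepoint intensity
#' matrix (linear scale) with its transcript identifiers, optional gene
#' symbol annotation, optional Affymetrix-style detection calls, and the
#' shared [time_grid()]. Values are stored as a plain numeric matrix with
#' transcript IDs as row names and time labels (minutes) as column names.
#'
#' @param values Numeric matrix, transcripts x timepoints, linear scale.
#' @param donor_id Donor label (single string).
#' @param grid A [time_grid()] matching `ncol(values)`.
#' @param transcript_ids Character vector of unique transcript/probeset IDs;
#'   defaults to `rownames(values)`.
#' @param gene_symbols Optional character vector of gene symbols aligned to
#'   transcripts. Affymetrix-style multi-gene annotations use `"///"` as a
#'   separator; `NA` marks transcripts with no symbol.
#' @param flags Optional character matrix of detection calls, same shape as
#'   `values`, cells in `P` (present), `M` (marginal), `A` (absent);
#'   case-insensitive.
#'
#' @return An object of class `expr_dataset`.
#' @seealso [read_expression_table()], [flag_filter()], [intensity_filter()]
#' @export
expr_dataset <- function(values, donor_id, grid,
                         transcript_ids = rownames(values),
                         gene_symbols = NULL, flags = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix (transcripts x timepoints).")
  }
  if (!all(is.finite(values))) {
    rlang::abort("`values` must be finite.")
  }
  stopifnot(inherits(grid, "time_grid"))
  if (ncol(values) != grid$n_points) {
    rlang::abort(sprintf(
      "`values` has %d columns but the grid has %d points.",
      ncol(values), grid$n_points
    ))
  }
  if (is.null(transcript_ids)) {
    rlang::abort("Transcript IDs are required (row names or `transcript_ids`).")
  }
  transcript_ids <- as.character(transcript_ids)
  if (length(transcript_ids) != nrow(values)) {
    rlang::abort("`transcript_ids` length must match the number of rows.")
  }
  dup <- unique(transcript_ids[duplicated(transcript_ids)])
  if (length(dup) > 0L) {
    rlang::abort(sprintf(
      "Duplicated transcript IDs are not allowed: %s",
      paste(utils::head(dup, 5L), collapse = ", ")
    ))
  }
  if (!is.null(gene_symbols)) {
    gene_symbols <- as.character(gene_symbols)
    if (length(gene_symbols) != nrow(values)) {
      rlang::abort("`gene_symbols` length must match the number of rows.")
    }
  }
  if (!is.null(flags)) {
    flags <- validate_flags(flags, dim(values))
  }
  dimnames(values) <- list(transcript_ids, format(grid_times(grid), trim = TRUE))
  if (!is.null(flags)) dimnames(flags) <- dimnames(values)
  structure(
    list(
      donor_id = as.character(donor_id)[1L],
      transcript_ids = transcript_ids,
      gene_symbols = gene_symbols,
      values = values,
      flags = flags,
      grid = grid
    ),
    class = "expr_dataset"
  )
}

validate_flags <- function(flags, dims) {
  if (!is.matrix(flags)) {
    rlang::abort("`flags` must be a matrix of detection calls.")
  }
  if (!identical(dim(flags), dims)) {
    rlang::abort("`flags` must have the same shape as `values`.")
  }
  flags <- toupper(as.character(flags))
  bad <- setdiff(unique(flags), c("P", "M", "A"))
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "Detection calls must be P, M or A; found: %s",
      paste(bad, collapse = ", ")
    ))
  }
  matrix(flags, nrow = dims[1L], ncol = dims[2L])
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf(
    "<expr_dataset> donor '%s': %d transcripts x %d timepoints (%s flags, %s symbols)\n",
    x$donor_id, nrow(x$values), ncol(x$values),
    if (is.null(x$flags)) "no" else "with",
    if (is.null(x$gene_symbols)) "no" else "with"
  ))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Extract the intensity or flag matrix from a dataset
#'
#' @param ds An [expr_dataset()].
#' @return `expr_values()` the numeric matrix; `expr_flags()` the detection
#'   call matrix or `NULL`.
#' @export
expr_values <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  ds$values
}

#' @rdname expr_values
#' @export
expr_flags <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  ds$flags
}

# Restrict a dataset to a subset of transcript ids (keeps the given order).
subset_dataset <- function(ds, ids) {
  idx <- match(ids, ds$transcript_ids)
  if (anyNA(idx)) {
    rlang::abort("Internal error: subset ids not present in dataset.")
  }
  expr_dataset(
    values = ds$values[idx, , drop = FALSE],
    donor_id = ds$donor_id,
    grid = ds$grid,
    transcript_ids = ds$transcript_ids[idx],
    gene_symbols = if (is.null(ds$gene_symbols)) NULL else ds$gene_symbols[idx],
    flags = if (is.null(ds$flags)) NULL else ds$flags[idx, , drop = FALSE]
  )
}

#' Tidy a dataset into long form
#'
#' @param x An [expr_dataset()].
#' @param ... Unused.
#' @return A tibble with columns `donor_id`, `transcript_id`, `gene_symbol`
#'   (if annotated), `time_min`, `value` and `flag` (if present).
#' @importFrom generics tidy
#' @method tidy expr_dataset
#' @export
tidy.expr_dataset <- function(x, ...) {
  times <- grid_times(x$grid)
  out <- tibble::tibble(
    donor_id = x$donor_id,
    transcript_id = rep(x$transcript_ids, each = length(times)),
    time_min = rep(times, times = nrow(x$values)),
    value = as.vector(t(x$values))
  )
  if (!is.null(x$gene_symbols)) {
    out <- dplyr::mutate(out,
      gene_symbol = rep(x$gene_symbols, each = length(times)),
      .after = "transcript_id"
    )
  }
  if (!is.null(x$flags)) {
    out$flag <- as.vector(t(x$flags))
  }
  out
}

#' Back-transform log2-scale values to linear scale
#'
#' Expression matrices normalized on the log2 scale are mapped elementwise
#' through `2^x` so that all downstream filtering and model fitting operate
#' on absolute (linear-scale) intensities.
#'
#' @param values Numeric vector or matrix of log2-scale values (finite).
#' @return Object of the same shape with `2^values`; strictly positive.
#' @examples
#' delog_transform(c(0, 1, 10)) # 1, 2, 1024
#' @export
delog_transform <- function(values) {
  if (!is.numeric(values)) {
    rlang::abort("`values` must be numeric.")
  }
  if (!all(is.finite(values))) {
    rlang::abort("`values` must be finite to back-transform.")
  }
  2^values
}

#' Read a delimited expression (or flag) table
#'
#' Reads a TSV/CSV matrix with one header row of time labels, one row per
#' transcript, the transcript ID in the first column and, optionally, a
#' gene-symbol column named `gene_symbol` in the second position. The number
#' of numeric columns must equal `grid$n_points`.
#'
#' @param path Path to the delimited file. The delimiter is inferred from
#'   the extension (`.csv` = comma, otherwise tab).
#' @param donor_id Donor label attached to the dataset.
#' @param grid A [time_grid()] describing the expected columns.
#' @param flags_path Optional path to a companion detection-call table with
#'   identical layout (cells `P`/`M`/`A`).
#' @param delog If `TRUE`, values are read as log2 scale and back-transformed
#'   with [delog_transform()].
#'
#' @return An [expr_dataset()].
#' @export
read_expression_table <- function(path, donor_id, grid, flags_path = NULL,
                                  delog = FALSE) {
  stopifnot(inherits(grid, "time_grid"))
  raw <- read_matrix_table(path, n_points = grid$n_points, numeric_values = TRUE)
  values <- raw$values
  if (delog) values <- delog_transform(values)
  flags <- NULL
  if (!is.null(flags_path)) {
    fraw <- read_matrix_table(flags_path, n_points = grid$n_points,
                              numeric_values = FALSE)
    if (!identical(fraw$ids, raw$ids)) {
      rlang::abort("Flag table transcript IDs do not match the expression table.")
    }
    flags <- fraw$values
  }
  expr_dataset(
    values = values, donor_id = donor_id, grid = grid,
    transcript_ids = raw$ids, gene_symbols = raw$symbols, flags = flags
  )
}

read_matrix_table <- function(path, n_points, numeric_values = TRUE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path))
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  prob <- readr::problems(tab)
  if (nrow(prob) > 0L) {
    rlang::abort(sprintf(
      "Malformed table %s: row %d expected %s columns, got %s.",
      path, prob$row[1L], prob$expected[1L], prob$actual[1L]
    ))
  }
  if (ncol(tab) < 2L) {
    rlang::abort(sprintf("Table %s needs an ID column plus data columns.", path))
  }
  ids <- as.character(tab[[1L]])
  symbols <- NULL
  data_cols <- tab[-1L]
  if (identical(tolower(names(tab)[2L]), "gene_symbol")) {
    symbols <- as.character(tab[[2L]])
    symbols[symbols %in% c("", "NA")] <- NA_character_
    data_cols <- tab[-(1:2)]
  }
  if (ncol(data_cols) != n_points) {
    rlang::abort(sprintf(
      "Table %s has %d data columns but the grid expects %d timepoints.",
      path, ncol(data_cols), n_points
    ))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    rlang::abort(sprintf(
      "Duplicated transcript IDs in %s: %s",
      path, paste(utils::head(dup, 5L), collapse = ", ")
    ))
  }
  m <- as.matrix(data_cols)
  if (numeric_values) {
    suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m), ncol = ncol(m)))
    if (anyNA(num)) {
      bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
      rlang::abort(sprintf(
        "Non-numeric cell in %s at data row %d, column %d ('%s').",
        path, bad[["row"]], bad[["col"]], m[bad[["row"]], bad[["col"]]]
      ))
    }
    m <- num
  }
  list(ids = ids, symbols = symbols, values = m)
}

#' Write a dataset back to delimited text
#'
#' Inverse of [read_expression_table()]: writes the intensity matrix (and,
#' with `what = "flags"`, the detection calls) as a TSV with time labels as
#' the header.
#'
#' @param ds An [expr_dataset()].
#' @param path Output file path.
#' @param what Either `"values"` or `"flags"`.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(ds, path, what = c("values", "flags")) {
  stopifnot(inherits(ds, "expr_dataset"))
  what <- match.arg(what)
  m <- if (what == "values") ds$values else ds$flags
  if (is.null(m)) {
    rlang::abort("Dataset has no flags to write.")
  }
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  names(df) <- format(grid_times(ds$grid), trim = TRUE)
  df <- tibble::add_column(df, transcript_id = ds$transcript_ids, .before = 1L)
  if (!is.null(ds$gene_symbols)) {
    df <- tibble::add_column(df, gene_symbol = ds$gene_symbols, .after = 1L)
  }
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
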