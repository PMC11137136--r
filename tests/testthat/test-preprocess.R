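test_that("delog transform is elementwise 2^x and rejects non-finite input", {
  expect_identical(delog_transform(0), 1)
  expect_identical(delog_transform(10), 1024)
  expect_identical(delog_transform(c(1, 2, 3)), c(2, 4, 8))
  m <- matrix(c(0, 1, 2, 3), 2)
  expect_identical(delog_transform(m), 2^m)
  expect_true(all(delog_transform(matrix(rnorm(20), 4)) > 0))
  expect_error(delog_transform(c(1, NA)), "finite")
  expect_error(delog_transform(Inf), "finite")
})

test_that("flag filter drops all-absent transcripts and keeps any P/M call", {
  ds <- make_filter_dataset()
  res <- flag_filter(ds)
  expect_setequal(res$report$removed_ids[[1]], "drop_mean")
  expect_identical(res$dataset$transcript_ids,
                   c("keep_high", "drop_peak", "keep_marginal"))
  expect_identical(res$report$n_input, 4L)
  expect_identical(res$report$n_kept, 3L)
})

test_that("flag filter refuses to run silently without flags", {
  ds <- make_filter_dataset()
  ds$flags <- NULL
  expect_error(flag_filter(ds), "use_flag_filter")
})

test_that("intensity filter enforces both mean and peak thresholds", {
  ds <- make_filter_dataset()
  res <- intensity_filter(ds)
  expect_setequal(res$report$removed_ids[[1]], c("drop_mean", "drop_peak"))
  # boundary: mean exactly 50 and peak exactly 100 is kept (>=, not >)
  grid5 <- time_grid(n_points = 5)
  boundary <- expr_dataset(
    rbind(edge = c(100, 37.5, 37.5, 37.5, 37.5)), "d", grid5
  )
  expect_identical(intensity_filter(boundary)$dataset$transcript_ids, "edge")
  expect_error(intensity_filter(ds, mean_min = -1), "nonnegative")
})

test_that("filters are idempotent and composition is non-increasing", {
  ds <- make_filter_dataset()
  once <- flag_filter(ds)$dataset
  twice <- flag_filter(once)$dataset
  expect_identical(once$values, twice$values)
  i_once <- intensity_filter(once)$dataset
  i_twice <- intensity_filter(i_once)$dataset
  expect_identical(i_once$values, i_twice$values)
  pp <- preprocess_datasets(list(ds))
  counts <- pp$report[pp$report$rule != "intersection", ]
  expect_true(all(diff(c(counts$n_input[1], counts$n_kept)) <= 0))
})

test_that("donor intersection restricts to common ids in identical order", {
  grid5 <- time_grid(n_points = 5)
  mk <- function(ids, donor) {
    expr_dataset(matrix(200, length(ids), 5, dimnames = list(ids, NULL)),
                 donor, grid5)
  }
  out <- intersect_donors(list(mk(c("a", "b", "c"), "d1"),
                               mk(c("c", "b", "d"), "d2")))
  expect_identical(out[[1]]$transcript_ids, c("b", "c"))
  expect_identical(out[[1]]$transcript_ids, out[[2]]$transcript_ids)
  same <- intersect_donors(list(mk(c("b", "a"), "d1"), mk(c("a", "b"), "d2")))
  expect_identical(same[[1]]$transcript_ids, c("a", "b")) # canonical order
  expect_error(
    intersect_donors(list(mk(c("a"), "d1"), mk(c("b"), "d2"))),
    "intersection"
  )
})

test_that("expression tables round-trip through disk and reject bad input", {
  grid <- time_grid()
  truth <- synth_truth(n_true = 1, n_decoys = 3, noise_frac = 0, seed = 5)
  syn <- generate_screen_dataset(truth)
  dir <- withr::local_tempdir()
  write_synth_dataset(syn, dir)
  back <- read_expression_table(
    file.path(dir, "donor1_expression.tsv"), donor_id = "donor1", grid = grid,
    flags_path = file.path(dir, "donor1_flags.tsv")
  )
  expect_equal(unname(back$values), unname(syn$datasets[[1]]$values),
               tolerance = 1e-12)
  expect_identical(back$transcript_ids, syn$datasets[[1]]$transcript_ids)
  expect_true(all(back$flags == "P"))

  # wrong column count -> shape error naming the expectation
  bad <- file.path(dir, "bad.tsv")
  writeLines(c(paste(c("id", 1:18), collapse = "\t"),
               paste(c("tx1", rep("5", 18)), collapse = "\t")), bad)
  expect_error(read_expression_table(bad, "d", grid), "18 data columns")

  # non-numeric cell -> parse error locating the cell
  bad2 <- file.path(dir, "bad2.tsv")
  writeLines(c(paste(c("id", 1:19), collapse = "\t"),
               paste(c("tx1", rep("5", 18), "oops"), collapse = "\t")), bad2)
  expect_error(read_expression_table(bad2, "d", grid), "Non-numeric")

  # duplicated transcript id -> error naming it
  bad3 <- file.path(dir, "bad3.tsv")
  writeLines(c(paste(c("id", 1:19), collapse = "\t"),
               paste(c("ZNF331", rep("5", 19)), collapse = "\t"),
               paste(c("ZNF331", rep("6", 19)), collapse = "\t")), bad3)
  expect_error(read_expression_table(bad3, "d", grid), "ZNF331")
})

test_that("flag calls are case-insensitive and unknown symbols are rejected", {
  grid5 <- time_grid(n_points = 5)
  v <- matrix(200, 1, 5, dimnames = list("t1", NULL))
  lower <- expr_dataset(v, "d", grid5, flags = matrix("p", 1, 5))
  expect_true(all(lower$flags == "P"))
  expect_error(
    expr_dataset(v, "d", grid5, flags = matrix("X", 1, 5)),
    "P, M or A"
  )
})
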