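test_that("all2one fits every (input, output, donor) and excludes targets as inputs", {
  truth <- synth_truth(n_true = 1, n_decoys = 9, noise_frac = 0, seed = 3)
  syn <- generate_screen_dataset(truth)
  cfg <- screen_config(target_output_ids = truth$target_ids)
  fits <- all2one(syn$datasets, cfg)
  expect_identical(nrow(fits), 10L * 2L * 2L) # 10 inputs x 2 outputs x 2 donors
  expect_false(any(fits$input_id %in% truth$target_ids))
  # noiseless true regulator: perfect fit in both donors, both outputs
  true_fits <- dplyr::filter(fits, input_id == "TRUEREG_001")
  expect_identical(nrow(true_fits), 4L)
  expect_equal(true_fits$fitness, rep(100, 4), tolerance = 1e-6)
  expect_error(
    all2one(syn$datasets, screen_config("NOT_A_TRANSCRIPT")),
    "NOT_A_TRANSCRIPT"
  )
})

test_that("consistency filter keeps agreeing signs and discards flips or degeneracy", {
  fits <- make_fit_records(3)
  # input 1: consistent everywhere (kept)
  # input 2: sign flip in donor2 on one output (discarded)
  fits$sign[fits$input_id == "IN_00002" & fits$donor_id == "donor2" &
              fits$output_id == "O1"] <- "repressor"
  # input 3: degenerate fit in one donor (discarded)
  fits$degenerate[fits$input_id == "IN_00003" & fits$donor_id == "donor1" &
                    fits$output_id == "O2"] <- TRUE
  res <- consistency_filter(fits)
  expect_identical(unique(res$fits$input_id), "IN_00001")
  expect_setequal(res$discarded$input_id, c("IN_00002", "IN_00003"))
  expect_identical(
    res$discarded$reason[res$discarded$input_id == "IN_00002"],
    "sign disagreement across donors"
  )
  expect_identical(
    res$discarded$reason[res$discarded$input_id == "IN_00003"],
    "degenerate fit"
  )
})

test_that("ranking is a fitness-descending permutation with stated tie-breaks", {
  fits <- make_fit_records(3, outputs = "O1")
  fits$fitness <- rep(c(50, 60, 40), 2)
  cfg <- screen_config("T", ranking_donor = "donor2")
  tb <- rank_models(fits, cfg)
  expect_identical(tb$rank, 1:3)
  expect_identical(tb$input_id, c("IN_00002", "IN_00001", "IN_00003"))
  expect_true(all(diff(tb$fitness) <= 0))
  # per-donor fitness map carried along
  expect_true(all(c("fitness_donor1", "fitness_donor2") %in% names(tb)))
  # ties break lexicographically by input id
  fits$fitness <- 50
  tb2 <- rank_models(fits, cfg)
  expect_identical(tb2$input_id, sort(tb2$input_id))
  # every retained model appears exactly once
  expect_identical(nrow(dplyr::distinct(tb, input_id, output_id)), nrow(tb))
})

test_that("percentile cut keeps the ceiling of fraction times rows", {
  fits <- make_fit_records(100, outputs = "O1")
  tb <- rank_models(fits, screen_config("T", ranking_donor = "donor2"))
  expect_identical(nrow(top_percentile(tb, 0.025)), 3L) # ceil(2.5)
  expect_identical(nrow(top_percentile(tb, 1)), 100L)
  expect_error(top_percentile(tb, 0), "fraction")
})

test_that("gene collapsing keeps the best-ranked row per identity", {
  tb <- tibble::tibble(
    rank = 1:5,
    input_id = c("p1", "p2", "p3", "p4", "p5"),
    gene_symbol = c("G1", NA, "G1", "G2", NA),
    fitness = c(90, 80, 70, 60, 50)
  )
  out <- collapse_to_genes(tb)
  expect_identical(nrow(out), 4L) # G1 (rank 1), p2, G2, p5
  expect_identical(attr(out, "n_collapsed"), 1L)
  expect_identical(out$rank[out$identity == "G1"], 1L)
  # all-unique symbols: identity mapping
  tb2 <- dplyr::mutate(tb, gene_symbol = paste0("G", 1:5))
  expect_identical(nrow(collapse_to_genes(tb2)), 5L)
})

test_that("candidate filters drop multi-gene annotations and off-window delays", {
  tb <- tibble::tibble(
    rank = 1:4,
    input_id = sprintf("p%d", 1:4),
    gene_symbol = c("A///B", "C", "D", NA),
    delay_min = c(40, 100, 40, 20),
    fitness = c(60, 55, 50, 45)
  )
  out <- candidate_filters(tb)
  expect_identical(out$input_id, c("p3", "p4")) # p1 multi-gene, p2 delay 100
  wide <- candidate_filters(tb, delay_window_min = c(0, 100),
                            exclude_multi_gene = FALSE)
  expect_identical(nrow(wide), 4L)
})

test_that("screen output is deterministic given identical inputs and config", {
  run_once <- function() {
    truth <- synth_truth(n_true = 1, n_decoys = 30, noise_frac = 0.1, seed = 77)
    syn <- generate_screen_dataset(truth)
    cfg <- screen_config(target_output_ids = truth$target_ids)
    res <- run_pipeline(syn$datasets, cfg, preprocess = FALSE)
    path <- tempfile(fileext = ".tsv")
    readr::write_tsv(tibble::as_tibble(res$full_table), path, progress = FALSE)
    on.exit(unlink(path))
    readLines(path)
  }
  expect_identical(run_once(), run_once())
})

test_that("count bookkeeping: retained inputs times outputs equals ranked models", {
  truth <- synth_truth(n_true = 2, n_decoys = 60, noise_frac = 0.1, seed = 19)
  syn <- generate_screen_dataset(truth)
  cfg <- screen_config(target_output_ids = truth$target_ids)
  res <- run_pipeline(syn$datasets, cfg, preprocess = FALSE)
  m <- res$manifest
  expect_identical(m$n_models_ranked, m$n_inputs_retained * m$n_outputs)
  expect_identical(m$n_fits,
                   m$n_inputs_screened * m$n_outputs * m$n_donors)
  expect_identical(m$n_inputs_screened,
                   m$n_inputs_retained + m$n_inputs_discarded)
})
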