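Package: regscreen
Title: Genome-Scale Screening of Candidate Upstream Regulators from
    Time-Series Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks every transcript in a time-series expression dataset as a
    candidate upstream regulator of one target gene. Each candidate is
    scored by fitting a delayed first-order linear dynamical model (single
    input, single output, constant offset) by one-step-ahead least squares,
    scanning a grid of input delays, and measuring how well the fitted model
    reproduces the target trajectory in free-run simulation with a
    normalized root-mean-square fitness. Includes microarray-style
    preprocessing (detection-call and intensity filters, cross-donor
    intersection), a cross-donor activator/repressor consistency filter,
    percentile cutoffs and gene-level collapsing of the ranked list, and a
    seeded synthetic-data generator with known ground-truth regulators for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
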