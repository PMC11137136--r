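# Shared test fixtures, all built in code.

default_grid <- regscreen::time_grid()

# A small dataset with hand-chosen flag/intensity patterns.
make_filter_dataset <- function(grid = regscreen::time_grid(n_points = 5)) {
  n <- grid$n_points
  values <- rbind(
    keep_high = rep(200, n),               # passes everything
    drop_mean = c(120, rep(30, n - 1)),    # mean < 50, max >= 100
    drop_peak = rep(60, n),                # mean >= 50, max < 100
    keep_marginal = c(150, rep(120, n - 1))
  )
  flags <- matrix("P", nrow = 4, ncol = n)
  flags[2, ] <- "A"                        # all-absent -> flag-filtered
  flags[4, ] <- c("M", rep("A", n - 1))    # one marginal call -> kept
  regscreen::expr_dataset(values, donor_id = "d1", grid = grid, flags = flags)
}

# Deterministic regulator/target pair generated by known parameters.
make_true_pair <- function(seed = 1, alpha = 0.6, beta = 0.4, gamma = 20,
                           d = 0, noise_sd = 0,
                           grid = regscreen::time_grid()) {
  u <- regscreen::generate_input_signal(grid, seed = seed, kind = "smooth")
  y <- regscreen::generate_target(u, alpha = alpha, beta = beta, gamma = gamma,
                                  d = d, y0 = 300, noise_sd = noise_sd,
                                  seed = seed + 10000)
  data.frame(u = u, y = y)
}

# Independent least-squares oracle: derivative-free coordinate descent on
# the one-step squared prediction error. Each coordinate step evaluates the
# objective on a 3-point grid and jumps to the parabola's vertex, which is
# the exact per-coordinate minimizer of a quadratic; sweeps are repeated
# until the parameters stop moving.
brute_force_ols <- function(y_now, u_lag, y_next) {
  obj <- function(p) sum((y_next - p[1] * y_now - p[2] * u_lag - p[3])^2)
  p <- c(0, 0, 0)
  h <- 1
  for (sweep in 1:1000) {
    p_old <- p
    for (j in 1:3) {
      f0 <- obj(p)
      pp <- p; pp[j] <- p[j] + h; fp <- obj(pp)
      pm <- p; pm[j] <- p[j] - h; fm <- obj(pm)
      curv <- fp - 2 * f0 + fm
      if (curv > 0) p[j] <- p[j] - 0.5 * h * (fp - fm) / curv
    }
    if (max(abs(p - p_old)) < 1e-13 * max(1, max(abs(p)))) break
  }
  p
}

# Fabricate a consistent two-donor fit table with the given input count.
make_fit_records <- function(n_inputs, outputs = c("O1", "O2"),
                             donors = c("donor1", "donor2"), seed = 1) {
  inputs <- sprintf("IN_%05d", seq_len(n_inputs))
  grid <- expand.grid(input_id = inputs, output_id = outputs,
                      donor_id = donors, stringsAsFactors = FALSE)
  set.seed(seed)
  tibble::as_tibble(grid) |>
    dplyr::mutate(
      gene_symbol = NA_character_,
      delay_min = sample(seq(0, 100, 20), dplyr::n(), replace = TRUE),
      delay_steps = delay_min / 20,
      alpha = stats::runif(dplyr::n(), 0.3, 0.9),
      beta = stats::runif(dplyr::n(), 0.1, 0.5),
      gamma = 0,
      sign = "activator",
      fitness = stats::runif(dplyr::n(), -20, 90),
      n_fit_points = 19L,
      degenerate = FALSE
    )
}
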