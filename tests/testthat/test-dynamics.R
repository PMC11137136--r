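test_that("input shifting truncates the usable window instead of padding", {
  expect_identical(shift_input(c(1, 2, 3, 4), 0), c(1, 2, 3, 4))
  expect_identical(shift_input(c(1, 2, 3, 4), 1), c(1, 2, 3))
  u19 <- seq_len(19)
  expect_length(shift_input(u19, 5), 14) # 100 min at 20-min steps
  expect_error(shift_input(c(1, 2, 3, 4), 3), "usable window")
})

test_that("fitness score matches its closed form, is <= 100, and 100 iff exact", {
  y <- c(1, 2, 3)
  expect_equal(fitness_score(y, y), 100)
  expect_equal(fitness_score(y, rep(mean(y), 3)), 0)
  expect_equal(fitness_score(y, c(1, 2, 4)), 100 * (1 - 1 / sqrt(2)),
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:25) {
    yo <- rnorm(19); yh <- rnorm(19)
    f <- fitness_score(yo, yh)
    expect_lte(f, 100)
    expect_false(isTRUE(all.equal(f, 100)))
  }
  expect_warning(out <- fitness_score(rep(2, 5), rnorm(5)), "constant")
  expect_true(is.nan(out))
})

test_that("free-run simulation follows the recursion and never re-anchors", {
  expect_equal(simulate_pairwise(rep(0, 5), 1, 0, 0, d = 0, y0 = 7), rep(7, 5))
  u <- c(3, 1, 4, 1, 5)
  expect_equal(simulate_pairwise(u, 0, 1, 0, d = 0, y0 = 9),
               c(9, u[1:4])) # pure relay
  expect_equal(simulate_pairwise(c(2, 2, 2), 0.5, 1, 0, d = 0, y0 = 0),
               c(0, 2, 3))
})

test_that("noiseless pairs are recovered exactly at every delay in the grid", {
  for (d in 0:5) {
    pair <- make_true_pair(seed = 100 + d, alpha = 0.55, beta = -0.35,
                           gamma = 400, d = d)
    fit <- fit_delay_scan(pair)
    expect_identical(fit$delay_min, d * 20)
    expect_equal(fit$alpha, 0.55, tolerance = 1e-6)
    expect_equal(fit$beta, -0.35, tolerance = 1e-6)
    expect_equal(fit$gamma, 400, tolerance = 1e-6)
    expect_equal(fit$fitness, 100, tolerance = 1e-6)
    expect_identical(fit$sign, "repressor")
    expect_identical(fit$n_fit_points, 19L - d)
  }
})

test_that("degenerate pairs are flagged and excluded from ranking quantities", {
  const <- data.frame(u = rep(5, 19), y = rep(3, 19))
  fit <- fit_pairwise(const)
  expect_true(fit$degenerate)
  expect_true(is.nan(fit$fitness))
  expect_true(is.na(fit$sign))
  scan <- fit_delay_scan(const)
  expect_true(scan$degenerate)
})

test_that("output noise unrelated to the input yields near-zero fitness", {
  set.seed(202)
  vals <- replicate(40, {
    pair <- data.frame(u = runif(19, 100, 500), y = rnorm(19))
    fit_pairwise(pair)$fitness
  })
  expect_lt(median(vals), 40) # far from a meaningful fit
})

test_that("one-step OLS matches a brute-force minimizer of the PEM criterion", {
  set.seed(303)
  for (i in 1:50) {
    n <- sample(10:19, 1)
    u <- rnorm(n); y <- rnorm(n)
    fit <- fit_pairwise(data.frame(u = u, y = y), d = 0)
    oracle <- brute_force_ols(y[1:(n - 1)], u[1:(n - 1)], y[2:n])
    expect_equal(c(fit$alpha, fit$beta, fit$gamma), oracle,
                 tolerance = 1e-8)
  }
})

test_that("best-fit fitness is invariant to affine input transforms", {
  pair <- make_true_pair(seed = 9, alpha = 0.6, beta = 0.4, gamma = 30, d = 1)
  base <- fit_delay_scan(pair)
  for (cfg in list(c(3, 100), c(0.2, -50), c(-2, 400))) {
    tr <- pair
    tr$u <- cfg[1] * pair$u + cfg[2]
    fit <- fit_delay_scan(tr)
    expect_equal(fit$fitness, base$fitness, tolerance = 1e-8)
    expect_identical(fit$delay_min, base$delay_min)
    expected_sign <- if (cfg[1] > 0) base$sign else
      setdiff(c("activator", "repressor"), base$sign)
    expect_identical(fit$sign, expected_sign)
  }
})

test_that("delay-scan ties break toward the smallest delay", {
  # constant input: every delay gives the same (degenerate-input-free) AR fit
  set.seed(17)
  y <- cumsum(rnorm(19)) + 50
  u <- 200 + 10 * seq_len(19) # linear ramp: delayed copies are affine-equal
  fits <- lapply(0:5, function(d) fit_pairwise(data.frame(u = u, y = y), d = d))
  best <- fit_delay_scan(data.frame(u = u, y = y))
  fitness <- vapply(fits, `[[`, numeric(1), "fitness")
  expect_identical(best$delay_steps,
                   (0:5)[which(fitness == max(fitness))[1]])
})

test_that("expected fitness degrades monotonically with observation noise", {
  noise_fracs <- c(0, 0.05, 0.10, 0.20)
  mean_fit <- vapply(noise_fracs, function(nf) {
    vals <- vapply(1:50, function(s) {
      u <- generate_input_signal(time_grid(), seed = 5000 + s, kind = "smooth")
      y0 <- generate_target(u, 0.6, 0.4, 50, d = 1, y0 = 300, noise_sd = 0)
      sdn <- nf * sd(y0)
      y <- generate_target(u, 0.6, 0.4, 50, d = 1, y0 = 300,
                           noise_sd = sdn, seed = 7000 + s)
      fit_delay_scan(data.frame(u = u, y = y))$fitness
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_fit) < 0))
})

test_that("bulk vectorized fitting agrees with the single-pair path", {
  truth <- synth_truth(n_true = 2, n_decoys = 20, noise_frac = 0.1, seed = 31)
  syn <- generate_screen_dataset(truth)
  ds <- syn$datasets[[1]]
  y <- ds$values["TARGET_T1", ]
  inputs <- setdiff(ds$transcript_ids, truth$target_ids)
  U <- ds$values[inputs, , drop = FALSE]
  for (d in c(0L, 3L)) {
    bulk <- regscreen:::fit_bulk_delay(U, y, d)
    for (i in sample(seq_along(inputs), 5)) {
      single <- fit_pairwise(data.frame(u = U[i, ], y = y), d = d)
      expect_equal(bulk$alpha[i], single$alpha, tolerance = 1e-10)
      expect_equal(bulk$beta[i], single$beta, tolerance = 1e-10)
      expect_equal(bulk$gamma[i], single$gamma, tolerance = 1e-10)
      expect_equal(bulk$fitness[i], single$fitness, tolerance = 1e-10)
    }
  }
})
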