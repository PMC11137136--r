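#' Deterministic synthetic regulator/decoy input signals
#'
#' `kind = "smooth"` draws a strictly positive low-order Fourier series (at
#' most 3 harmonics over the sampled span, amplitudes decaying as 1/h^2)
#' rescaled to a random intensity range inside 100-1000 arbitrary units -
#' the shape of a clean, slowly varying transcript trajectory. `kind =
#' "noise"` draws positive white noise over the same range. Both are fully
#' determined by `seed`.
#'
#' @param grid A [time_grid()].
#' @param seed Integer seed for this one signal.
#' @param kind `"smooth"` or `"noise"`.
#' @return Numeric series of length `grid$n_points`, strictly positive.
#' @export
generate_input_signal <- function(grid, seed, kind = c("smooth", "noise")) {
  stopifnot(inherits(grid, "time_grid"))
  kind <- match.arg(kind)
  n <- grid$n_points
  with_seed(seed, {
    lo <- stats::runif(1L, 100, 300)
    hi <- lo + stats::runif(1L, 200, 700)
    if (kind == "noise") {
      return(stats::runif(n, lo, hi))
    }
    span <- grid$step_min * n # period of the fundamental harmonic
    t <- grid_times(grid) - grid$start_min
    h <- 1:3
    amp <- stats::runif(3L, 0.5, 1) / h^2
    phase <- stats::runif(3L, 0, 2 * pi)
    raw <- colSums(amp * sin(outer(2 * pi * h / span, t) + phase))
    if (max(raw) - min(raw) < 1e-9) { # degenerate draw; fall back to harmonic 1
      raw <- sin(2 * pi * t / span)
    }
    lo + (raw - min(raw)) / (max(raw) - min(raw)) * (hi - lo)
  })
}

#' Generate a noisy target trajectory from a known pairwise model
#'
#' Free-runs the discrete model `y[k+1] = alpha y[k] + beta u[k-d] + gamma`
#' from `y0` over the full grid (the input is held at its first value for
#' the lead-in samples before the delay), then adds independent Gaussian
#' observation noise of standard deviation `noise_sd` to every sample.
#' `noise_sd = 0` returns the exact model trajectory, so a round trip
#' through [fit_delay_scan()] recovers the generating parameters.
#'
#' @param u Input series.
#' @param alpha,beta,gamma Generating discrete parameters.
#' @param d Delay in steps.
#' @param y0 Initial target value.
#' @param noise_sd Observation-noise standard deviation (intensity units).
#' @param seed Integer seed for the noise draw.
#' @return Numeric series of length `length(u)`.
#' @export
generate_target <- function(u, alpha, beta, gamma, d = 0L, y0,
                            noise_sd = 0, seed = 1L) {
  d <- check_delay_steps(d, length(u))
  if (noise_sd < 0) rlang::abort("`noise_sd` must be nonnegative.")
  u_ext <- c(rep(u[1L], d), u)[seq_along(u)] # input held at baseline pre-delay
  n <- length(u)
  y <- numeric(n)
  y[1L] <- y0
  for (k in seq_len(n - 1L)) {
    y[k + 1L] <- alpha * y[k] + beta * u_ext[k] + gamma
  }
  if (noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  }
  y
}

#' Ground-truth specification for a synthetic two-donor screen
#'
#' Fixes everything the generator needs: the grid, the number of decoys,
#' the true regulators with per-donor dynamical parameters (signs shared
#' across donors by construction, so true regulators survive the
#' cross-donor consistency filter), optional sign-inconsistent regulators
#' (opposite gain signs in the two donors - these must be discarded by the
#' filter), and the observation-noise level as a fraction of each noiseless
#' target trajectory's standard deviation.
#'
#' @param n_true Number of true regulators.
#' @param n_decoys Number of decoy transcripts (independent smooth signals).
#' @param n_inconsistent Number of planted sign-inconsistent regulators.
#' @param noise_frac Observation noise SD as a fraction of the noiseless
#'   target SD (default 0.10, a realistically noisy microarray series).
#' @param seed Master seed; every transcript derives its own substream.
#' @param grid A [time_grid()] (default 19 points every 20 min).
#' @param repressor_fraction Probability that a true regulator is a
#'   repressor (negative gain); default 0.5.
#' @return A `synth_truth` list with fields `regulators` (tibble of
#'   per-donor generating parameters), `n_decoys`, `noise_frac`, `seed`,
#'   `grid`, `target_ids`, `donor_ids`.
#' @export
synth_truth <- function(n_true = 1L, n_decoys = 199L, n_inconsistent = 0L,
                        noise_frac = 0.10, seed = 1L,
                        grid = time_grid(), repressor_fraction = 0.5) {
  stopifnot(inherits(grid, "time_grid"))
  if (noise_frac < 0) rlang::abort("`noise_frac` must be nonnegative.")
  n_true <- as.integer(n_true); n_decoys <- as.integer(n_decoys)
  n_inconsistent <- as.integer(n_inconsistent)
  if (n_true < 0 || n_decoys < 0 || n_inconsistent < 0) {
    rlang::abort("Counts must be nonnegative.")
  }
  donor_ids <- c("donor1", "donor2")
  max_d <- min(5L, grid$n_points - 4L)
  regs <- with_seed(substream_seed(seed, 0L), {
    n_reg <- n_true + n_inconsistent
    if (n_reg == 0L) {
      tibble::tibble(
        regulator_id = character(), consistent = logical(),
        donor_id = character(), alpha = numeric(), beta = numeric(),
        gamma = numeric(), delay_steps = integer()
      )
    } else {
      base <- tibble::tibble(
        regulator_id = c(
          sprintf("TRUEREG_%03d", seq_len(n_true)),
          sprintf("INCONS_%03d", seq_len(n_inconsistent))
        ),
        consistent = rep(c(TRUE, FALSE), c(n_true, n_inconsistent)),
        alpha = stats::runif(n_reg, 0.45, 0.75),
        beta_sign = ifelse(stats::runif(n_reg) < repressor_fraction, -1, 1),
        beta_mag = stats::runif(n_reg, 0.3, 0.6),
        delay_steps = sample.int(max_d + 1L, n_reg, replace = TRUE) - 1L
      )
      purrr::map_dfr(seq_along(donor_ids), function(j) {
        jitter <- stats::runif(n_reg, 0.85, 1.15)
        sign_j <- ifelse(base$consistent | j == 1L, base$beta_sign,
                         -base$beta_sign)
        tibble::tibble(
          regulator_id = base$regulator_id,
          consistent = base$consistent,
          donor_id = donor_ids[j],
          alpha = pmin(base$alpha * stats::runif(n_reg, 0.95, 1.05), 0.9),
          beta = sign_j * base$beta_mag * jitter,
          gamma = 0, # set later so target levels stay positive
          delay_steps = base$delay_steps
        )
      })
    }
  })
  structure(
    list(
      regulators = regs,
      n_decoys = n_decoys,
      noise_frac = noise_frac,
      seed = as.integer(seed),
      grid = grid,
      target_ids = c("TARGET_T1", "TARGET_T2"),
      donor_ids = donor_ids
    ),
    class = "synth_truth"
  )
}

#' Generate a complete two-donor synthetic screening dataset
#'
#' Builds, per donor, an [expr_dataset()] emulating a stimulation time
#' course in which a module of co-regulated upstream genes drives one
#' target gene measured by two probesets:
#'
#' * a latent noiseless target trajectory (smooth, positive, donor
#'   specific) defines the donor's target dynamics;
#' * the two target transcripts are affine copies of that trajectory (two
#'   probesets of the same transcript differ in scale and offset) plus
#'   independent Gaussian observation noise of SD `noise_frac` times the
#'   noiseless trajectory's SD;
#' * each true regulator transcript is constructed so that its delayed
#'   first-order pairwise model holds exactly against the latent
#'   trajectory with that regulator's generating parameters - a
#'   co-regulated module in which every member carries the target's
#'   dynamical signature at its own gain, offset and delay. Sign-
#'   inconsistent regulators do the same with opposite gain signs in the
#'   two donors;
#' * decoys are independent smooth signals.
#'
#' All detection flags are `P`. Every transcript draws from its own seed
#' substream, so a transcript's series does not depend on how many other
#' transcripts are generated.
#'
#' @param truth A [synth_truth()] specification.
#' @return A list with `datasets` (list of two [expr_dataset()]) and
#'   `truth` (the input, with realized per-target noise SDs appended as
#'   `noise_sd_realized`).
#' @export
generate_screen_dataset <- function(truth) {
  stopifnot(inherits(truth, "synth_truth"))
  grid <- truth$grid
  n <- grid$n_points
  reg_ids <- unique(truth$regulators$regulator_id)
  decoy_ids <- if (truth$n_decoys > 0L) {
    sprintf("DECOY_%05d", seq_len(truth$n_decoys))
  } else {
    character()
  }
  input_ids <- c(reg_ids, decoy_ids)
  all_ids <- c(input_ids, truth$target_ids)
  noise_log <- list()
  gamma_log <- list()
  datasets <- purrr::map(seq_along(truth$donor_ids), function(j) {
    donor <- truth$donor_ids[j]
    # latent noiseless target trajectory for this donor
    z <- latent_target_signal(
      grid, seed = substream_seed(truth$seed, 900000L + j)
    )
    regs_j <- dplyr::filter(truth$regulators, .data$donor_id == donor)
    U <- matrix(NA_real_, nrow = length(input_ids), ncol = n,
                dimnames = list(input_ids, NULL))
    for (r in seq_len(nrow(regs_j))) {
      inv <- invert_regulator_series(
        z, alpha = regs_j$alpha[r], beta = regs_j$beta[r],
        d = regs_j$delay_steps[r]
      )
      U[regs_j$regulator_id[r], ] <- inv$u
      gamma_log[[length(gamma_log) + 1L]] <<- tibble::tibble(
        regulator_id = regs_j$regulator_id[r], donor_id = donor,
        gamma = inv$gamma
      )
    }
    for (i in seq_along(decoy_ids)) {
      U[decoy_ids[i], ] <- generate_input_signal(
        grid, seed = substream_seed(truth$seed, 1000L * j + length(reg_ids) + i),
        kind = "smooth"
      )
    }
    targets <- matrix(NA_real_, nrow = 2L, ncol = n,
                      dimnames = list(truth$target_ids, NULL))
    for (o in 1:2) {
      probe <- with_seed(substream_seed(truth$seed, 910000L + 10L * j + o), {
        list(scale = if (o == 1L) 1 else stats::runif(1L, 0.6, 1.4),
             offset = if (o == 1L) 0 else stats::runif(1L, 0, 100))
      })
      y <- probe$scale * z + probe$offset
      noise_sd <- truth$noise_frac * stats::sd(y)
      if (noise_sd > 0) {
        y <- y + with_seed(
          substream_seed(truth$seed, 950000L + 10L * j + o),
          stats::rnorm(n, sd = noise_sd)
        )
      }
      noise_log[[length(noise_log) + 1L]] <<- tibble::tibble(
        donor_id = donor, output_id = truth$target_ids[o],
        noise_sd_realized = noise_sd
      )
      targets[o, ] <- y
    }
    values <- rbind(U, targets)
    expr_dataset(
      values = values,
      donor_id = donor,
      grid = grid,
      transcript_ids = all_ids,
      flags = matrix("P", nrow = length(all_ids), ncol = n)
    )
  })
  truth$noise_sd_realized <- dplyr::bind_rows(noise_log)
  if (length(gamma_log) > 0L) {
    realized <- dplyr::bind_rows(gamma_log)
    truth$regulators <- truth$regulators |>
      dplyr::select(-"gamma") |>
      dplyr::left_join(realized, by = c("regulator_id", "donor_id"))
  }
  list(datasets = datasets, truth = truth)
}

# Latent target trajectory: like a smooth input signal but spectrally
# richer (5 harmonics), reflecting a target that integrates several
# upstream drives; no single low-order decoy can span it by chance.
latent_target_signal <- function(grid, seed) {
  n <- grid$n_points
  with_seed(seed, {
    lo <- stats::runif(1L, 100, 300)
    hi <- lo + stats::runif(1L, 200, 700)
    span <- grid$step_min * n
    t <- grid_times(grid) - grid$start_min
    h <- 1:5
    amp <- stats::runif(5L, 0.6, 1) / h^1.5
    phase <- stats::runif(5L, 0, 2 * pi)
    raw <- colSums(amp * sin(outer(2 * pi * h / span, t) + phase))
    lo + (raw - min(raw)) / (max(raw) - min(raw)) * (hi - lo)
  })
}

# Construct a regulator series u such that
#   z[k+1] = alpha z[k] + beta u[k-d] + gamma
# holds exactly on the fitting window, with gamma chosen so u is strictly
# positive at a realistic mean intensity. The trailing d+1 samples of u are
# never consumed at delay d; they extend the series smoothly by repeating
# the last constrained value.
invert_regulator_series <- function(z, alpha, beta, d) {
  n <- length(z)
  w <- z[2:n] - alpha * z[1:(n - 1)] # required drive beta*u[k-d] + gamma
  m <- n - 1L - d                    # constrained input samples
  raw <- w[(d + 1L):(n - 1L)] / beta # u up to the additive gamma/beta shift
  level <- 100 + (max(raw) - min(raw))
  u_head <- raw - mean(raw) + level
  gamma <- mean(w[(d + 1L):(n - 1L)]) - beta * level
  stopifnot(length(u_head) == m)
  list(u = c(u_head, rep(u_head[m], n - m)), gamma = gamma)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf(
    "<synth_truth> %d true + %d inconsistent regulators, %d decoys, noise %.0f%% of target SD, seed %d\n",
    sum(x$regulators$consistent[!duplicated(x$regulators$regulator_id)]),
    sum(!x$regulators$consistent[!duplicated(x$regulators$regulator_id)]),
    x$n_decoys, 100 * x$noise_frac, x$seed
  ))
  invisible(x)
}

#' Serialize a synthetic dataset to the TSV dialect the reader consumes
#'
#' Writes per-donor expression and flag tables plus a JSON truth manifest,
#' producing files that round-trip through [read_expression_table()].
#'
#' @param synth Result of [generate_screen_dataset()].
#' @param dir Output directory (created if needed).
#' @return Tibble of written file paths, invisibly.
#' @export
write_synth_dataset <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_dfr(synth$datasets, function(ds) {
    expr_path <- file.path(dir, sprintf("%s_expression.tsv", ds$donor_id))
    flag_path <- file.path(dir, sprintf("%s_flags.tsv", ds$donor_id))
    write_expression_table(ds, expr_path, what = "values")
    write_expression_table(ds, flag_path, what = "flags")
    tibble::tibble(donor_id = ds$donor_id, expression = expr_path, flags = flag_path)
  })
  truth <- synth$truth
  manifest <- list(
    seed = truth$seed,
    noise_frac = truth$noise_frac,
    n_decoys = truth$n_decoys,
    grid = truth$grid[c("start_min", "step_min", "n_points")],
    target_ids = truth$target_ids,
    donor_ids = truth$donor_ids,
    regulators = truth$regulators
  )
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
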