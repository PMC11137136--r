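# regscreen

Genome-scale screening of candidate upstream regulators of a single target
gene from short, uniformly sampled time-series expression data.

## The problem

Given per-donor expression matrices (thousands of transcripts × ~19
timepoints sampled every 20 minutes), which transcripts are plausible
*upstream regulators* of one gene of interest? `regscreen` answers this with
an "all-to-one" sweep: every transcript is tried, one at a time, as the
input of a small dynamical model of the target, and candidates are ranked
by how well their model reproduces the target's trajectory.

## The model

Each (candidate `u`, target `y`) pair is described by a delayed first-order
linear time-invariant system

```
dy/dt = a · y(t) + b · u(t − τ)
```

with a constant offset added, where `a` is the target's self-regulation
rate, `b` the input gain — positive `b` calls the candidate an *activator*,
negative a *repressor* — and `τ` a transcriptional delay scanned over
{0, 20, 40, 60, 80, 100} minutes to absorb unmeasured intermediate steps
(translation, complex formation, promoter binding). At the uniform sampling
step the model is identified in its exact discrete form

```
y[k+1] = alpha · y[k] + beta · u[k − d] + gamma
```

by ordinary least squares on the one-step-ahead prediction error (the exact
minimizer of the prediction-error criterion for this model class). The
fitted model is then judged by *free-run simulation* — recursing from the
first usable sample using only the input, never re-anchoring to data — with
the normalized root-mean-square fitness

```
fitness = 100 · (1 − ‖y − ŷ‖ / ‖y − ȳ‖)
```

100 means a perfect reproduction, 0 no better than the constant mean, and
negative values (kept, never clamped) a model worse than the mean.

The screen then:

1. filters transcripts (detection-call filter: drop all-Absent rows;
   intensity filter: mean ≥ 50 and peak ≥ 100; cross-donor intersection);
2. fits every (input, output, donor) triple at each delay and keeps the
   best delay per triple (ties go to the shorter delay);
3. discards inputs whose activator/repressor sign disagrees between donors
   for any target transcript;
4. ranks the remaining models by the designated donor's fitness and cuts
   at a top percentile (default 2.5%, with a ceiling rule);
5. optionally collapses transcripts to distinct genes and applies
   shortlist filters (single-gene annotation, delay within 20–60 min).

## Worked example

The package ships a seeded synthetic-data generator with known ground
truth, so the whole pipeline is testable without any download. Two donors,
2 true regulators planted among 98 decoys, observation noise at 10% of the
target's SD:

```r
library(regscreen)

truth <- synth_truth(n_true = 2, n_decoys = 98, noise_frac = 0.1, seed = 2024)
syn   <- generate_screen_dataset(truth)
cfg   <- screen_config(target_output_ids = truth$target_ids)
res   <- run_pipeline(syn$datasets, cfg, preprocess = FALSE)
res$table
#> <screen_table> 3 ranked models (ranking donor: donor2)
#> # A tibble: 3 x 16
#>    rank input_id    gene_symbol output_id donor_id delay_min delay_steps alpha
#> 1     1 TRUEREG_001 <NA>        TARGET_T1 donor2          20           1 0.644
#> 2     2 TRUEREG_001 <NA>        TARGET_T2 donor2          20           1 0.686
#> 3     3 TRUEREG_002 <NA>        TARGET_T2 donor2          60           3 0.462
```

Both planted regulators land in the top 2.5% of the 100 ranked models
(`res$manifest`: 100 inputs screened, 50 retained after the cross-donor
sign-consistency discard, 100 models ranked, 3 kept at the 2.5% cut).
A single pair can be fitted directly:

```r
pair <- data.frame(
  u = expr_values(syn$datasets[[2]])["TRUEREG_001", ],
  y = expr_values(syn$datasets[[2]])["TARGET_T1", ]
)
fit <- fit_delay_scan(pair)
fit
#> <pairwise_fit> u -> y (donor)
#>   delay 20 min | fitness 90.49% | activator
#>   alpha 0.6439, beta 0.3376, gamma -152.8 (continuous a = -0.02201 /min)
```

The fitted delay (20 min) and gain sign match the generating truth
(`beta = 0.339`, one-step delay); the fitness of ~90% reflects the 10%
observation noise. `tidy()`, `glance()` and `autoplot()` methods turn fits
and screen tables into tibbles and ggplots; `run_pipeline_files()` and the
thin CLI in `inst/cli/regscreen.R` (subcommands `run`, `synth`, `filter`,
`report`) run the same pipeline from delimited text files.

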