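# pfseq — pooled fitness profiling under periodic environments

`pfseq` analyses genome-scale pooled competition experiments in which
barcoded deletion mutants proliferate through serial dilution in steady or
periodically fluctuating environments (e.g. alternating normal medium N and
salt medium S with periods of 6–42 h on a 3-h transfer grid). It is aimed at
groups running BAR-Seq-style competitions who want to ask not only *how fit
is each mutant in each environment*, but whether fitness in a fluctuating
environment is more than the time average of fitness in its steady
components.

The package covers the full path from reads to biological calls:

* **Simulation** — a forward simulator of the whole experiment
  (`sim_config()`, `sim_truth()`, `simulate_experiment()`, `emit_fastq()`,
  `simulate_cytometry()`) with known ground truth, so every estimator has a
  parameter-recovery test surface.
* **Demultiplexing** — error-correcting decoding of 9-nt Hamming-coded
  sample indices and Levenshtein-tolerant uptag mapping
  (`decode_index()`, `map_barcode()`, `build_counts()`).
* **Processing** — sample/mutant filtering, day-0 imputation, and
  median-of-ratios + variance-stabilizing normalization
  (`filter_samples()`, `filter_mutants()`, `impute_missing_day0()`,
  `normalize_counts()`).
* **Fitness** — relative fitness per generation against an artificial
  wild-type reference built from neutral deletions,

  $$w = \left(\frac{M_e/M_b}{WT_e/WT_b}\right)^{1/g}, \qquad g = 24,$$

  the time-average null $w_\mathrm{expected} = w_N^{f_N} w_S^{f_S}$ and the
  inhomogeneity ratio $\mathrm{dev} = w_\mathrm{obs}/w_\mathrm{exp}$
  (`fitness_table()`, `expected_fitness()`, `dev_table()`), plus the
  genetic-variance decomposition $V_G = V_T - V_E$ with bootstrap CIs
  (`genetic_variance()`).
* **Inference** — a per-mutant negative-binomial GLM,
  $\log\lambda = \mathrm{offset} + \beta_1 t_N + \beta_2 t_S +
  \beta_3 N_\mathrm{changes}$, whose environment-change term tests
  deviation from time-average fitness; q-values control the FDR
  (`fit_inhomogeneity_glms()`, `call_inhomogeneous()`).
* **Selection calls** — antagonistic pleiotropy (opposite fitness signs in
  the two media plus Mahalanobis-distance deviation from the bulk, all
  replicates concordant) and transgressive fitness (3-of-4 replicates
  beyond the steady-condition envelope), each with a permutation null
  (`ap_calls()`, `transgressive_calls()`, `permutation_null_*()`).
* **Cytometry** — density gating, automatic GFP valley thresholding and
  fitness from GFP+/GFP− counts for individual competitions
  (`gate_events()`, `find_gfp_threshold()`, `cytometry_fitness()`).

Everything is data-frame-in / tibble-out and pipe-friendly; fitted objects
have `tidy()` / `glance()` methods and `autoplot()` visualizations. The
`run_pipeline()` orchestrator (and the thin CLI in
`inst/scripts/pfseq.R`) chains the stages from a single YAML/list config
with a reproducibility manifest.

## Worked example

Simulate a 300-mutant pool (11 neutral reference strains, ~10 genuinely
inhomogeneous mutants with a per-change log increment of 0.05) under steady
N, steady S and a 6-h oscillation, then recover them:

```r
library(pfseq)
library(dplyr)

truth <- sim_truth(300, sd_log_w = 0.03, seed = 1)
truth$beta3[290:300] <- 0.05          # planted inhomogeneous mutants
cfg <- sim_config(n_mutants = 300, depth_per_sample = 1e6,
                  nb_dispersion = 0.02,
                  conditions = data.frame(condition = c("N", "S", "NS6"),
                                          period_h = c(0, 0, 6)),
                  seed = 1)
sim <- simulate_experiment(cfg, truth)
#> <pf_sim> 300 mutants x 48 samples (3 conditions, 4 replicates)

norm <- normalize_counts(sim$counts)
fit  <- fitness_table(norm, sim$samples, neutral_ids(truth))
dev_table(fit, sim$design) |> arrange(desc(dev)) |> head(4)
#> # A tibble: 4 × 4
#>   mutant_id w_obs w_exp   dev
#> 1 mut00295   1.05 0.991  1.06
#> 2 mut00299   1.07 1.01   1.06
#> 3 mut00293   1.08 1.02   1.06
#> 4 mut00290   1.06 1.00   1.06
```

The planted mutants top the inhomogeneity ranking: their observed fitness in
the oscillating regime exceeds the time-average expectation by ~6% per
generation. The GLM turns this into calibrated calls:

```r
fits   <- fit_inhomogeneity_glms(norm, sim$samples, period_h = 6)
called <- call_inhomogeneous(fits, fdr = 0.01, method = "BH")
length(called)                                        # 11 mutants called
sum(called %in% truth$mutant_id[truth$beta3 > 0])     # all 11 truly planted

genetic_variance(filter(fit, condition == "S"), seed = 1)
#> <pf_vardecomp> V_T = 0.00101, V_E = 5.43e-05, V_G = 0.000953
#>                [0.00079, 0.00112] (300 mutants, 1000 bootstraps)
```

Here ~94% of the fitness variance in steady S is genetic (between-mutant),
matching the simulated log-fitness spread of 0.03
($0.03^2 \approx 0.0009$), and the replicate noise floor is an order of
magnitude smaller.

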