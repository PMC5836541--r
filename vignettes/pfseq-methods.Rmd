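---
title: "Methods: pooled fitness profiling under periodic environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled fitness profiling under periodic environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfseq)
library(dplyr)
```

## The experimental system

`pfseq` analyses pooled competition experiments in which thousands of
barcoded deletion mutants proliferate together through serial dilution,
either in a steady medium or in an environment that alternates periodically
between two media (here called N, a normal synthetic medium, and S, the same
medium with 0.2 M NaCl). Cultures are transferred every 3 hours on a robotic
platform; the population doubles roughly once per transfer, giving eight
generations per day. Periodic regimes alternate N and S with periods of 6,
12, 18, 24 or 42 h on that 3-h grid, and every condition is run in four
replicate populations. Populations are sampled at days 0-3 and strain
abundances are read out by sequencing each strain's chromosomal uptag
barcode (BAR-Seq): a PCR primer carries a 9-nt sample index from a
Hamming-distance-3 code, and the read layout is
`index9 + U1 + uptag + U2` with the universal flanks returned by
`barseq_flanks()`.

The scientific question is whether a mutant's proliferation in a fluctuating
environment is just the time average of its proliferation in the two steady
environments ("homogenized" fitness), or whether the *dynamics* — the number
of environmental transitions experienced — contribute on their own.

## Relative fitness and the homogenization null

Fitness is relative and per generation. For mutant $M$ with frequencies
$M_b, M_e$ at the beginning and end of the competition, and an artificial
wild-type reference with frequencies $WT_b, WT_e$,

$$ w = \left( \frac{M_e / M_b}{WT_e / WT_b} \right)^{1/g}, $$

with $g = 24$ generations between day 0 and day 3 (`fitness_w()`,
`fitness_table()`). The artificial wild type is the summed abundance of a
configurable set of deletion strains assumed neutral for growth (eleven in
the original design; `artificial_wt()`). Doubling time is ~10% longer in S
than in N; a condition-specific $g$ can be passed for robustness checks, and
$g$ is otherwise held at 24.

The time-average (homogenization) null states that fitness in a periodic
regime is the time-weighted geometric mean of the steady-condition fitness:

$$ w_\text{expected} = w_N^{f_N} \cdot w_S^{f_S}, \qquad
   \text{dev} = \frac{w_\text{observed}}{w_\text{expected}}, $$

where $f_N, f_S$ are the fractions of time spent in each medium
(`expected_fitness()`, `inhomogeneity_dev()`, `dev_table()`). All symmetric
periods give $f_N = f_S = 1/2$ over the three-day experiment; the 42-h
period splits 72 h into 42 h of S and 30 h of N.

Schedule bookkeeping is exact slot algebra (`schedule()`, `design_row()`):
exposure times are summed over 3-h slots, and the change count $N^\text{changes}$
counts medium switches at slot boundaries in $(0, 24d]$, evaluating the
boundary at the sampling time against the schedule's next slot. The day-0
switch out of the initialization medium is not counted; since the change
count enters the model linearly, the alternative convention would only shift
each mutant's change covariate by a constant and leave the test unchanged.

## The negative-binomial GLM for inhomogeneity

Counts for mutant $i$ in condition $c$ at day $d$ are modeled as negative
binomial with

$$ \log \lambda_i = \text{offset}_i + \beta_{i,1}\, t^N_{c,d}
   + \beta_{i,2}\, t^S_{c,d} + \beta_{i,3}\, N^\text{changes}_{c,d}, $$

one model per oscillating period, pooling that period's samples with the two
steady conditions (`fit_mutant_glm()`, `fit_inhomogeneity_glms()`). Exposure
times are in days, so $\beta_1, \beta_2$ are per-day log growth advantages
and $\beta_3$ is the per-change log-abundance increment. Under
homogenization $\beta_{i,3} = 0$, so its significance is the test of
inhomogeneity. Dispersion is estimated per mutant by alternating maximum
likelihood with the coefficients (`MASS::glm.nb`); data that are
under-dispersed for the NB family fall back to its Poisson limit.

Two calibration choices in this package deserve explanation, both validated
on null simulations:

* **Pooled day-0 offset.** The offset is the log median of the mutant's
  day-0 normalized counts, entered with a fixed coefficient of 1. Because
  every population is initialized identically and conditions only diverge
  after day 0, the default pools all day-0 samples into one per-mutant
  offset. Fixing instead a separate noisy offset per condition makes each
  condition's fitted slope absorb an independent error, which inflates the
  $\beta_3$ test dramatically (a third of null genes below $p = 0.05$ in our
  simulations); with a pooled offset, the offset's sampling error is a
  shared intercept shift that cancels in the balanced change-term contrast.
  `offset_mode = "per_condition"` remains available for designs whose day-0
  populations genuinely differ (e.g. imputed day-0 columns).
* **Quasi-likelihood moderation.** Maximum-likelihood NB dispersion
  estimates are biased low at ~48 observations, which makes raw Wald z
  statistics over-dispersed (sd ≈ 1.07 on ideal NB data). Wald z (and the
  LRT statistic) are therefore rescaled by the Pearson residual dispersion
  and referred to a t (respectively F) distribution on the residual degrees
  of freedom, the standard small-sample quasi-likelihood practice in count
  regression. With both choices, null p-values are uniform
  (Kolmogorov-Smirnov p ≈ 0.25-0.7 at 1,000 null genes).

P-values are converted to q-values with Storey's smoother-based $\pi_0$
estimate (`qvalues()`), falling back to Benjamini-Hochberg when $\pi_0$
cannot be estimated stably (fewer than 100 p-values, or an estimate outside
(0, 1]); `call_inhomogeneous()` thresholds q at the requested FDR, excluding
unconverged fits.

Because the assay measures *relative* abundance, a change effect shared by
the whole pool is unidentifiable: only deviation from the pool-average
behavior is estimated. Parameter-recovery simulations therefore plant
inhomogeneous genes as a small minority (200 in a pool of 6,004), matching
the original study's scale; planting a large fraction shifts the pool
average and attenuates every estimate, which is a property of relative
fitness itself, not of the estimator.

## Variance decomposition

Per condition, `genetic_variance()` computes, with population divisors
exactly as in the source formulas ($r$ replicates, $N$ mutants),

$$ V_T = \frac{1}{rN} \sum_{i}\sum_{j} (w_{ij} - \bar w)^2, \qquad
   V_E = \frac{1}{rN} \sum_{i}\sum_{j} (w_{ij} - \bar w_i)^2, \qquad
   V_G = V_T - V_E, $$

with a 95% percentile interval from 1,000 bootstrap resamples of mutants.
Algebraically $V_G$ equals the population variance of the per-mutant
replicate means. A consequence worth knowing: under pure replicate noise of
variance $s^2$ (no genetic signal), $V_G$ has expectation
$s^2 (N-1)/(rN) > 0$ — a noise floor, not zero — and the bootstrap interval
concentrates around that floor rather than around zero. The tests assert
this closed-form behavior; users comparing $V_G$ across conditions should
remember that conditions with larger replicate noise carry a larger floor.

## Antagonistic pleiotropy and transgressive fitness

Steady-condition replicates are combined into $(w_N, w_S)$ pairs
(`pair_replicates()`: the larger replicate set is randomly thinned to the
size of the smaller, then paired in index order). A bivariate Gaussian is
fitted to all pairs pooled over mutants (`fit_bivariate_gaussian()`); an
observation supports antagonistic pleiotropy if it shows an advantage in one
medium and a disadvantage in the other *and* lies more than 2 Mahalanobis
units from the fitted bulk (strictly greater; a point at distance exactly 2
is not an outlier). "Two standard deviations" is interpreted in Mahalanobis
units because the $(w_N, w_S)$ cloud is correlated; a per-axis rule is
available for sensitivity analysis. A mutant is called AP only when every
pair supports it (`call_AP()`, `ap_calls()`), and the expected chance count
comes from reassigning pairs to mutants at random, preserving the
pairs-per-mutant structure (`permutation_null_AP()`). AP magnitude is
$w_N / w_S$; per-period directions of selection and the
always-positive / always-negative / period-dependent / unclear classes
follow the mean ± SD rule (`classify_direction()`).

Transgressive fitness asks whether the oscillating-regime fitness escapes
the envelope of both steady conditions: at least 3 of 4 replicates above
$\max(\bar w_N + \sigma_N, \bar w_S + \sigma_S)$ or below
$\min(\bar w_N - \sigma_N, \bar w_S - \sigma_S)$ (`call_transgressive()`,
`transgressive_calls()`, with its own permutation null).

## Flow-cytometry competitions

Individual competitions of a GFP-tagged wild type against an untagged mutant
are analysed from FSC/SSC/FL1 event tables on the 0-1023 instrument scale
(`simulate_cytometry()` generates such tables with known mixing fractions).
`gate_events()` removes saturated events, estimates a 2-D Gaussian-kernel
density on (FSC, SSC) (`MASS::kde2d`, plug-in bandwidth) and keeps the
highest-density region containing 40% of events — implemented as the upper
level set by event count, one of the two readings of a "perimeter of peak
density"; samples with fewer than 2,000 input or 4,000 gated events are
rejected with a typed error. `find_gfp_threshold()` smooths the FL1
distribution and thresholds at the deepest valley between the two largest
modes, flagging unimodal (single-strain control) samples instead of
guessing. `cytometry_fitness()` then applies the same fitness estimator as
the pooled assay to the GFP−/GFP+ counts.

## The synthetic-data generator

`simulate_experiment()` forward-simulates the competition: growth is
per-slot (one generation per 3-h transfer, 8/day), so the expected abundance
of mutant $i$ at day $d$ is
$n_0 \, w_N^{g_N} w_S^{g_S} e^{\beta_3 N^\text{changes}}$. The inhomogeneity
effect is injected as the GLM's own alternative (a per-change log
increment) rather than through a mechanistic lag model, so parameter
recovery is exactly interpretable. Sequencing counts are NB-distributed
(Var $= \mu + \alpha\mu^2$, one $\alpha$ per experiment) and multinomially
resampled so each sample hits its target depth exactly; $\alpha = 0$ yields
deterministic real-valued expected counts, the noiseless mode used for
identifiability tests. Defaults follow the original design: 6,004 mutants,
~320 initial copies each, 4 replicates, 7 conditions, days 0-3, depth
2.6 million reads per sample, and $\alpha = 0.02$, a typical technical
overdispersion for BAR-Seq counts. Dilution-rate bookkeeping (0.85 / 0.55 /
0.32 by transfer type) is recorded but bottleneck resampling is off by
default, as the estimator is insensitive to it and the experimental
populations were kept above $2 \times 10^7$ cells. Whether periodic regimes
enter N or S first after the N initialization is not constrained by the
design; the generator exposes `first_condition` (default S) and all
analysis code is phase-agnostic.

What the generator does *not* emulate: initial library imbalance (all
mutants start at the same copy number, so day-0 replicate correlations on
simulated data are pure noise), PCR jackpotting, frequency-dependent
selection, de-novo mutation, and batch structure. Passing tests on this
generator therefore demonstrate correctness of the estimators under the
stated model, not robustness to every artefact of real libraries.

`emit_fastq()` writes the corresponding reads with per-base substitution
errors and `build_counts()` inverts them: Hamming-corrected index decoding
(unique codeword within distance 1), flank-anchored barcode extraction
tolerating one mismatch per flank and the 1-nt shift a single indel implies,
and Levenshtein-distance-1 barcode mapping in which ties at the minimal
distance are dropped rather than guessed — ambiguity between near-identical
tags must not become systematic misassignment.

## Normalization

`normalize_counts()` computes median-of-ratios size factors against the
geometric-mean pseudo-reference and, by default, the DESeq2
variance-stabilizing transformation with a locally fitted dispersion trend —
the transform used on the original data. For small tables where that fit is
infeasible the transform falls back to `log2(count/sizefactor + 0.5)`.
Downstream fitness and GLM fitting operate on the size-factor-scaled counts
(rounded to integers for the NB likelihood), so inference is invariant to
the choice between these smooth monotone recalibrations; the VST itself can
flatten at the extreme low-count boundary of its fitted trend, which is why
strict rank preservation is only guaranteed on the scaled and log2 scales.
Sample filtering discards samples only when they are both shallow
(< 300,000 reads) and poorly correlated with their replicates (default
floor 0.5, configurable — no universal value exists); mutants below 2,000
reads in total are discarded, thresholds strictly below as printed. Missing
day-0 columns are imputed as per-mutant medians over donor day-0 populations
grown in the same medium.

## Problem sizes and numerical choices

The test-suite and acceptance-script simulations use: 1,000 null genes for
p-value calibration plus 20 runs of 200 genes for FDR control; 200 planted
$\beta_3 = 0.05$ genes in a 6,004-mutant pool for effect recovery
(recovered mean within ±0.005; the ~0.003 shortfall predicted by the
pool-average compensation above is visible and accounted for); 500 genes at
depth $10^6$ with counting-noise-dominated dispersion ($\alpha$ = 5e-4) for
the homogenization identity, which is a property of the estimator rather
than of biological noise; 5 pooled runs of 100 mutants for the NB-noise
bias of $\hat w$ (the artificial-WT trace adds a common-mode shift to every
mutant in a run, so bias must be averaged over runs); 1,000 mutants for the
planted variance spread and 200 runs of 100 mutants for the noise-floor
behavior of $V_G$; and a planted-AP fixture of 50 antagonistic mutants among
1,050. Zero abundances receive a pseudo-abundance of 0.5 on the scaled
scale before ratios are formed; NB dispersion is floored at $10^{-8}$;
Mahalanobis outliers use a strict inequality at 2.

## Known limitations

* $V_G$ inherits the positive noise floor of its published estimator (see
  above); comparisons across conditions with unequal replicate noise are
  confounded by it.
* The GLM tests deviation from the pool-average change response; a
  pool-wide inhomogeneity is invisible to a relative-abundance assay.
* The per-condition-offset mode reproduces the original recipe exactly but
  is anticonservative for the change term; it is provided for comparison,
  not as the default.
* Barcode mapping assumes the read layout produced by `emit_fastq()`;
  arbitrary library layouts (downtags, paired ends, quality-aware
  correction) are out of scope.
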