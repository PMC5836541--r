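# Shared fixture builders. Everything is generated in code at test time.

three_conditions <- function() {
  data.frame(condition = c("N", "S", "NS6"), period_h = c(0, 0, 6))
}

# small deterministic competition: 20 mutants, 11 neutral, noiseless
tiny_noiseless_sim <- function(n = 20, depth = 1e5,
                               conditions = three_conditions(), seed = 1) {
  truth <- sim_truth(n, w_N = c(rep(1, 11), seq(0.95, 1.05, length.out = n - 11)),
                     w_S = c(rep(1, 11), seq(1.04, 0.96, length.out = n - 11)),
                     seed = seed)
  cfg <- sim_config(n_mutants = n, depth_per_sample = depth, nb_dispersion = 0,
                    conditions = conditions, seed = seed)
  simulate_experiment(cfg, truth)
}

# identity-ish normalization wrapper around a counts tibble for unit tests
# that do not care about size factors
as_norm <- function(counts) {
  sample_cols <- setdiff(names(counts), "mutant_id")
  structure(list(norm = counts, scaled = counts,
                 size_factors = stats::setNames(rep(1, length(sample_cols)),
                                                sample_cols),
                 method = "identity"),
            class = "pf_norm")
}

demo_library <- function(n = 8, seed = 11) {
  random_barcode_library(sprintf("mut%05d", seq_len(n)), seed = seed)
}

demo_codebook <- function(sample_ids, seed = 12) {
  make_index_codebook(sample_ids, seed = seed)
}
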