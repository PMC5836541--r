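#' Default pipeline configuration
#'
#' Encodes the study's printed parameter values: count floors of 300,000 per
#' sample and 2,000 per mutant, g = 24 generations, 1,000 bootstrap and
#' permutation resamples, Mahalanobis cutoff 2, 3-of-4 transgressivity
#' support, the 40% cytometry gate with 2,000/4,000 event floors, and the
#' simulator geometry of [sim_config()].
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
pipeline_defaults <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_mutants = 500, n_neutral = 11, depth_per_sample = 1e6,
                    nb_dispersion = 0.02, sd_log_w = 0.03,
                    frac_inhom = 0.05, beta3_effect = 0.05),
    process = list(min_total = 3e5, min_mutant_counts = 2000,
                   min_replicate_correlation = 0.5),
    fitness = list(g = 24, b_day = 0, e_day = 3),
    glm = list(period_h = 6, fdr = 1e-4),
    select = list(osc_condition = "NS6", n_perm = 1000, cutoff = 2,
                  min_support = 3),
    variance = list(n_bootstrap = 1000)
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> process -> fitness -> glm -> select from a single
#' configuration, writing each stage's outputs as TSV under `out_dir` and a
#' JSON run manifest recording seeds, parameters and per-stage input/output
#' sizes. Stages whose outputs already exist are skipped unless `force =
#' TRUE`, so deleting an intermediate file and re-running regenerates only
#' that stage and those downstream of it.
#'
#' @param config Configuration list (see [pipeline_defaults()]) or path to a
#'   YAML file with the same structure.
#' @param out_dir Output directory (created if needed).
#' @param force Recompute every stage even when outputs exist.
#' @return The run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_defaults(), out_dir, force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  manifest <- list(seed = cfg$seed, config = cfg, stages = list())
  wtsv <- function(x, f) utils::write.table(x, f, sep = "\t", quote = FALSE,
                                            row.names = FALSE)
  rtsv <- function(f) tibble::as_tibble(
    utils::read.table(f, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE))

  # -- simulate ---------------------------------------------------------
  sim_files <- p(c("counts.tsv", "samples.tsv", "truth.tsv"))
  if (force || !all(file.exists(sim_files))) {
    sc <- cfg$simulate
    n <- sc$n_mutants
    n_inhom <- round(sc$frac_inhom * n)
    truth <- sim_truth(n, n_neutral = sc$n_neutral, sd_log_w = sc$sd_log_w,
                       seed = cfg$seed)
    if (n_inhom > 0) {
      idx <- utils::tail(seq_len(n), n_inhom)  # non-neutral tail
      truth$beta3[idx] <- sc$beta3_effect
    }
    sim <- simulate_experiment(
      sim_config(n_mutants = n, depth_per_sample = sc$depth_per_sample,
                 nb_dispersion = sc$nb_dispersion, seed = cfg$seed),
      truth)
    wtsv(sim$counts, sim_files[1]); wtsv(sim$samples, sim_files[2])
    wtsv(truth, sim_files[3])
    manifest$stages$simulate <- list(ran = TRUE, n_mutants = n,
                                     n_samples = nrow(sim$samples))
  } else manifest$stages$simulate <- list(ran = FALSE)

  # -- process ----------------------------------------------------------
  proc_files <- p(c("scaled.tsv", "size_factors.tsv", "process_log.json"))
  if (force || !all(file.exists(proc_files)) ||
      any(file.mtime(proc_files) < max(file.mtime(sim_files)))) {
    counts <- rtsv(sim_files[1]); samples <- rtsv(sim_files[2])
    fs <- filter_samples(counts, samples, min_total = cfg$process$min_total,
                         min_replicate_correlation =
                           cfg$process$min_replicate_correlation)
    fm <- filter_mutants(fs$counts,
                         min_total_counts = cfg$process$min_mutant_counts)
    norm <- normalize_counts(fm)
    wtsv(norm$scaled, proc_files[1])
    wtsv(tibble::tibble(sample_id = names(norm$size_factors),
                        size_factor = norm$size_factors), proc_files[2])
    jsonlite::write_json(
      list(discarded_samples = fs$discarded$sample_id,
           discarded_mutants = attr(fm, "discarded"),
           normalization = norm$method),
      proc_files[3], auto_unbox = TRUE)
    wtsv(fs$samples, p("samples_kept.tsv"))
    manifest$stages$process <- list(ran = TRUE,
                                    n_mutants = nrow(fm),
                                    n_samples = nrow(fs$samples))
  } else manifest$stages$process <- list(ran = FALSE)

  # -- fitness ----------------------------------------------------------
  fit_file <- p("fitness.tsv")
  if (force || !file.exists(fit_file) ||
      file.mtime(fit_file) < max(file.mtime(proc_files))) {
    scaled <- rtsv(proc_files[1]); samples <- rtsv(p("samples_kept.tsv"))
    truth <- rtsv(sim_files[3])
    norm <- local_norm(scaled)
    fit <- fitness_table(norm, samples,
                         neutral_set = truth$mutant_id[truth$neutral],
                         g = cfg$fitness$g, b_day = cfg$fitness$b_day,
                         e_day = cfg$fitness$e_day)
    wtsv(fit, fit_file)
    manifest$stages$fitness <- list(ran = TRUE, n_rows = nrow(fit))
  } else manifest$stages$fitness <- list(ran = FALSE)

  # -- glm --------------------------------------------------------------
  glm_file <- p("glm_results.tsv")
  if (force || !file.exists(glm_file) ||
      file.mtime(glm_file) < file.mtime(fit_file)) {
    scaled <- rtsv(proc_files[1]); samples <- rtsv(p("samples_kept.tsv"))
    norm <- local_norm(scaled)
    fits <- fit_inhomogeneity_glms(norm, samples, period_h = cfg$glm$period_h)
    called <- call_inhomogeneous(fits, fdr = cfg$glm$fdr)
    qtab <- attr(called, "q_table")
    res <- fits |>
      dplyr::select(-"offsets", -"vcov") |>
      dplyr::left_join(qtab[, c("mutant_id", "q_beta3")], by = "mutant_id") |>
      dplyr::mutate(called = .data$mutant_id %in% called)
    wtsv(res, glm_file)
    manifest$stages$glm <- list(ran = TRUE, n_called = length(called),
                                period_h = cfg$glm$period_h)
  } else manifest$stages$glm <- list(ran = FALSE)

  # -- select -----------------------------------------------------------
  sel_files <- p(c("ap_calls.tsv", "transgressive_calls.tsv"))
  if (force || !all(file.exists(sel_files)) ||
      any(file.mtime(sel_files) < file.mtime(fit_file))) {
    fit <- rtsv(fit_file)
    ap <- ap_calls(fit, cutoff = cfg$select$cutoff, seed = cfg$seed)
    ap_null <- permutation_null_AP(ap, n_perm = cfg$select$n_perm,
                                   seed = cfg$seed,
                                   cutoff = cfg$select$cutoff)
    tg <- transgressive_calls(fit, osc_condition = cfg$select$osc_condition,
                              min_support = cfg$select$min_support)
    tg_null <- permutation_null_transgressivity(
      tg, n_perm = cfg$select$n_perm, seed = cfg$seed,
      min_support = cfg$select$min_support)
    wtsv(ap, sel_files[1]); wtsv(tg, sel_files[2])
    manifest$stages$select <- list(
      ran = TRUE, n_AP = sum(ap$is_AP),
      AP_null_expected = ap_null$expected,
      n_transgressive = sum(tg$direction != "none"),
      transgressive_null_expected = tg_null$expected)
  } else manifest$stages$select <- list(ran = FALSE)

  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

# wrap an on-disk scaled table back into a pf_norm object (size factors are
# already divided out, so they are identity here)
local_norm <- function(scaled) {
  sample_cols <- setdiff(names(scaled), "mutant_id")
  structure(list(norm = scaled, scaled = scaled,
                 size_factors = stats::setNames(rep(1, length(sample_cols)),
                                                sample_cols),
                 method = "precomputed"),
            class = "pf_norm")
}
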