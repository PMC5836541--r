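#' Configuration of a simulated pooled-competition experiment
#'
#' Defaults reproduce the geometry of the salt-oscillation study: seven
#' conditions (two steady media N and S plus alternating regimes with periods
#' 6, 12, 18, 24 and 42 h on a 3-h transfer grid), four replicate populations
#' per condition, sampling at days 0-3, ~320 initial copies of each of ~6,004
#' mutants, eight generations per day, and a per-sample sequencing depth of
#' ~2.6 million reads.
#'
#' @param n_mutants Number of mutants in the pool.
#' @param init_copies_per_mutant Mean initial copy number per mutant.
#' @param conditions Data frame with columns `condition`, `period_h`
#'   (`period_h = 0` marks a steady condition whose medium is the label).
#' @param n_replicates Replicate populations per condition.
#' @param transfer_interval_h Hours between transfers.
#' @param total_h Experiment duration after initialization (hours).
#' @param sampling_days Days at which populations are sequenced.
#' @param generations_per_day Cell generations per day (8: 3-h doubling).
#' @param depth_per_sample Expected total reads per sample.
#' @param nb_dispersion Negative-binomial dispersion alpha of sequencing
#'   counts (Var = mu + alpha mu^2). `0` means deterministic expected counts.
#' @param dilution_rates Fractions of the culture kept at each transfer type
#'   (media change only / + OD read / + sampling). Recorded for provenance;
#'   bottleneck resampling is off by default because the fitness estimator is
#'   insensitive to it.
#' @param bottlenecks Logical; apply multinomial bottlenecks at transfers.
#' @param first_condition Medium entered by periodic schedules at time 0.
#' @param seed Integer seed; all randomness in the simulation flows from it.
#' @return An object of class `"pf_sim_config"` (a named list).
#' @export
sim_config <- function(n_mutants = 6004,
                       init_copies_per_mutant = 320,
                       conditions = default_conditions(),
                       n_replicates = 4,
                       transfer_interval_h = 3,
                       total_h = 72,
                       sampling_days = 0:3,
                       generations_per_day = 8,
                       depth_per_sample = 2.6e6,
                       nb_dispersion = 0.02,
                       dilution_rates = c(media = 0.85, od = 0.55, sample = 0.32),
                       bottlenecks = FALSE,
                       first_condition = "S",
                       seed = 1L) {
  stopifnot(n_mutants >= 1, init_copies_per_mutant > 0,
            is.data.frame(conditions),
            all(c("condition", "period_h") %in% names(conditions)))
  if (depth_per_sample <= 0) stop("`depth_per_sample` must be > 0", call. = FALSE)
  if (nb_dispersion < 0) stop("`nb_dispersion` must be >= 0", call. = FALSE)
  if (any(dilution_rates <= 0 | dilution_rates > 1))
    stop("`dilution_rates` must lie in (0, 1]", call. = FALSE)
  bad <- conditions$period_h > 0 &
    conditions$period_h %% (2 * transfer_interval_h) != 0
  if (any(bad))
    stop("periods must be multiples of 2 * transfer_interval_h or 0", call. = FALSE)
  structure(
    list(n_mutants = as.integer(n_mutants),
         init_copies_per_mutant = init_copies_per_mutant,
         conditions = tibble::as_tibble(conditions),
         n_replicates = as.integer(n_replicates),
         transfer_interval_h = transfer_interval_h,
         total_h = total_h,
         sampling_days = sampling_days,
         generations_per_day = generations_per_day,
         depth_per_sample = depth_per_sample,
         nb_dispersion = nb_dispersion,
         dilution_rates = dilution_rates,
         bottlenecks = bottlenecks,
         first_condition = first_condition,
         seed = as.integer(seed)),
    class = "pf_sim_config"
  )
}

#' The seven conditions of the salt-oscillation design
#'
#' @return Tibble with columns `condition`, `period_h`.
#' @export
default_conditions <- function() {
  tibble::tibble(
    condition = c("N", "S", "NS6", "NS12", "NS18", "NS24", "NS42"),
    period_h = c(0, 0, 6, 12, 18, 24, 42)
  )
}

#' Ground-truth fitness parameters for a simulated pool
#'
#' Each mutant carries a relative growth multiplier per generation in each
#' steady medium (`w_N`, `w_S`) and an inhomogeneity effect `beta3`, the
#' log-abundance increment gained at every environmental change (0 for a
#' mutant whose fitness is homogenized in fluctuating environments). The
#' first `n_neutral` mutants are fitness-neutral (w = 1) and serve as the
#' artificial wild-type reference downstream.
#'
#' @param n_mutants Number of mutants.
#' @param n_neutral Number of neutral reference mutants (default 11).
#' @param w_N,w_S Fitness vectors recycled to length `n_mutants`, or `NULL`
#'   to draw them log-normally with standard deviation `sd_log_w`.
#' @param beta3 Per-change log-abundance increments (default 0).
#' @param sd_log_w SD of log fitness when drawing `w_N`/`w_S` (default 0.03).
#' @param seed Seed used only when fitness values are drawn.
#' @return Tibble of class `"pf_truth"`: `mutant_id`, `w_N`, `w_S`, `beta3`,
#'   `neutral`.
#' @export
sim_truth <- function(n_mutants, n_neutral = min(11L, n_mutants),
                      w_N = NULL, w_S = NULL, beta3 = 0,
                      sd_log_w = 0.03, seed = 1L) {
  stopifnot(n_mutants >= 1, n_neutral >= 0, n_neutral <= n_mutants)
  if (is.null(w_N) || is.null(w_S)) {
    set.seed(seed)
    if (is.null(w_N)) w_N <- exp(stats::rnorm(n_mutants, 0, sd_log_w))
    if (is.null(w_S)) w_S <- exp(stats::rnorm(n_mutants, 0, sd_log_w))
  }
  out <- tibble::tibble(
    mutant_id = sprintf("mut%05d", seq_len(n_mutants)),
    w_N = rep_len(w_N, n_mutants),
    w_S = rep_len(w_S, n_mutants),
    beta3 = rep_len(beta3, n_mutants),
    neutral = seq_len(n_mutants) <= n_neutral
  )
  if (any(out$w_N <= 0) || any(out$w_S <= 0))
    stop("fitness values must be positive", call. = FALSE)
  out$w_N[out$neutral] <- 1
  out$w_S[out$neutral] <- 1
  out$beta3[out$neutral] <- 0
  class(out) <- c("pf_truth", class(out))
  out
}

#' Neutral reference mutant ids of a truth table
#' @param truth A [sim_truth()] tibble.
#' @return Character vector of neutral mutant ids.
#' @export
neutral_ids <- function(truth) truth$mutant_id[truth$neutral]

#' Forward-simulate a pooled serial-dilution competition experiment
#'
#' Growth is modeled per transfer slot (one generation per 3-h slot, eight per
#' day): the expected abundance of mutant i in condition c at day d is
#' `n0 * w_N^g_N * w_S^g_S * exp(beta3 * n_changes)`, with `g_N`, `g_S` the
#' generations elapsed in each medium and `n_changes` the number of medium
#' switches since day 0. Sequencing counts are drawn NB(mu, alpha) around the
#' depth-scaled expected frequencies and then multinomially resampled so each
#' sample's total equals its depth; with `nb_dispersion = 0` the expected
#' (real-valued) counts are returned unperturbed.
#'
#' @param cfg A [sim_config()].
#' @param truth A [sim_truth()] table with one row per mutant.
#' @return A list of class `"pf_sim"`: `counts` (tibble, `mutant_id` plus one
#'   column per sample), `samples` (sample sheet: `sample_id`, `condition`,
#'   `period_h`, `day`, `replicate`), `truth`, and `design` (the
#'   [design_table()] used).
#' @examples
#' cfg <- sim_config(n_mutants = 20, depth_per_sample = 1e4, seed = 42,
#'                   conditions = data.frame(condition = c("N", "S", "NS6"),
#'                                           period_h = c(0, 0, 6)))
#' sim <- simulate_experiment(cfg, sim_truth(20, seed = 42))
#' dim(sim$counts)
#' @export
simulate_experiment <- function(cfg, truth) {
  stopifnot(inherits(cfg, "pf_sim_config"))
  if (!is.data.frame(truth) || nrow(truth) != cfg$n_mutants)
    stop("`truth` must have one row per mutant", call. = FALSE)
  if (cfg$n_mutants < 1) stop("empty mutant set", call. = FALSE)
  set.seed(cfg$seed)

  scheds <- purrr::pmap(list(cfg$conditions$condition, cfg$conditions$period_h),
                        function(cond, p)
                          schedule(cond, p,
                                   transfer_interval_h = cfg$transfer_interval_h,
                                   first_condition = cfg$first_condition,
                                   total_h = cfg$total_h))
  design <- design_table(scheds, days = cfg$sampling_days)
  gen_per_h <- cfg$generations_per_day / 24

  samples <- tidyr::expand_grid(
    condition = cfg$conditions$condition,
    day = cfg$sampling_days,
    replicate = seq_len(cfg$n_replicates)
  ) |>
    dplyr::left_join(cfg$conditions, by = "condition") |>
    dplyr::mutate(sample_id = sprintf("%s_d%d_r%d", .data$condition,
                                      .data$day, .data$replicate)) |>
    dplyr::select("sample_id", "condition", "period_h", "day", "replicate")

  n0 <- cfg$init_copies_per_mutant
  mat <- matrix(0, nrow = cfg$n_mutants, ncol = nrow(samples),
                dimnames = list(truth$mutant_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    row <- design[design$condition == samples$condition[j] &
                    design$day == samples$day[j], ]
    g_N <- row$t_N * gen_per_h
    g_S <- row$t_S * gen_per_h
    a <- n0 * truth$w_N^g_N * truth$w_S^g_S * exp(truth$beta3 * row$n_changes)
    mu <- a / sum(a) * cfg$depth_per_sample
    if (cfg$nb_dispersion == 0) {
      mat[, j] <- mu
    } else {
      y <- stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
      if (sum(y) == 0) y <- rep(1, length(mu))
      mat[, j] <- stats::rmultinom(1, size = round(cfg$depth_per_sample),
                                   prob = y / sum(y))[, 1]
    }
  }

  counts <- tibble::tibble(mutant_id = truth$mutant_id) |>
    dplyr::bind_cols(tibble::as_tibble(mat))
  structure(list(counts = counts, samples = samples, truth = truth,
                 design = design, config = cfg),
            class = "pf_sim")
}

#' @export
print.pf_sim <- function(x, ...) {
  cat(sprintf("<pf_sim> %d mutants x %d samples (%d conditions, %d replicates)\n",
              nrow(x$counts), nrow(x$samples),
              dplyr::n_distinct(x$samples$condition),
              max(x$samples$replicate)))
  invisible(x)
}
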