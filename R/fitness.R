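#' Artificial wild-type abundance per sample
#'
#' Combines (sums) the size-factor-scaled abundances of deletion strains
#' assumed neutral for growth into a pseudo wild-type reference trace.
#'
#' @param norm A [normalize_counts()] object, or a tibble of scaled counts
#'   (`mutant_id` + sample columns).
#' @param neutral_set Character vector of neutral mutant ids (the study used
#'   11 pseudogene / no-phenotype deletions).
#' @return Tibble: `sample_id`, `wt_abundance`.
#' @export
artificial_wt <- function(norm, neutral_set) {
  scaled <- if (inherits(norm, "pf_norm")) norm$scaled else norm
  present <- intersect(neutral_set, scaled$mutant_id)
  if (length(present) == 0)
    stop("no neutral reference mutants present in the table", call. = FALSE)
  sample_cols <- setdiff(names(scaled), "mutant_id")
  sub <- scaled[scaled$mutant_id %in% present, sample_cols]
  tibble::tibble(sample_id = sample_cols,
                 wt_abundance = unname(colSums(as.matrix(sub))))
}

#' Relative fitness from frequency changes over g generations
#'
#' `w = ((M_e / M_b) / (WT_e / WT_b))^(1/g)`: the per-generation growth
#' multiplier of a mutant relative to the wild-type reference, from their
#' frequencies at the beginning (b) and end (e) of the competition. Because
#' the frequencies share each sample's denominator, abundances can be passed
#' directly.
#'
#' @param M_b,M_e Mutant frequencies (or abundances) at beginning and end.
#' @param WT_b,WT_e Wild-type frequencies at beginning and end.
#' @param g Generations elapsed between the two time points (default 24).
#' @return Relative fitness w (vectorized).
#' @examples
#' fitness_w(0.01, 0.02, 0.5, 0.5)  # doubling relative to WT: 2^(1/24)
#' @export
fitness_w <- function(M_b, M_e, WT_b, WT_e, g = 24) {
  if (g < 1) stop("`g` must be >= 1", call. = FALSE)
  if (any(c(M_b, M_e, WT_b, WT_e) <= 0))
    stop("frequencies must be positive; apply a pseudo-abundance first",
         call. = FALSE)
  ((M_e / M_b) / (WT_e / WT_b))^(1 / g)
}

#' Time-average expected fitness in a fluctuating environment
#'
#' The homogenization null: `w_expected = w_N^f_N * w_S^f_S`, the geometric
#' mean of the steady-condition fitness values weighted by the fractions of
#' time spent in each medium.
#'
#' @param w_N,w_S Fitness in steady N and steady S.
#' @param f_N,f_S Fractions of time spent in N and S (`f_N + f_S = 1`).
#' @return Expected fitness (vectorized).
#' @export
expected_fitness <- function(w_N, w_S, f_N, f_S) {
  if (any(w_N <= 0) || any(w_S <= 0))
    stop("fitness values must be positive", call. = FALSE)
  if (any(abs(f_N + f_S - 1) > 1e-8))
    stop("`f_N + f_S` must equal 1", call. = FALSE)
  w_N^f_N * w_S^f_S
}

#' Fitness inhomogeneity ratio
#'
#' `dev = w_observed / w_expected`; `dev = 1` means fitness in the
#' fluctuating environment is fully explained by the time average of the
#' steady-condition fitness values.
#'
#' @param w_observed Fitness measured in the periodic environment.
#' @param w_expected Time-average expectation from [expected_fitness()].
#' @return The ratio dev (vectorized).
#' @export
inhomogeneity_dev <- function(w_observed, w_expected) {
  if (any(w_expected <= 0)) stop("`w_expected` must be positive", call. = FALSE)
  w_observed / w_expected
}

#' Per-mutant relative fitness for every condition and replicate
#'
#' Applies [fitness_w()] to size-factor-scaled abundances between a beginning
#' and an end day within each replicate population, against the artificial
#' wild-type built from `neutral_set`. Zero abundances receive a
#' pseudo-abundance (default 0.5 on the scaled-count scale).
#'
#' @param norm A [normalize_counts()] object.
#' @param samples Sample sheet (`sample_id`, `condition`, `period_h`, `day`,
#'   `replicate`).
#' @param neutral_set Neutral mutant ids for the artificial wild type.
#' @param g Generations between the endpoints (default 24, i.e. days 0 to 3
#'   at 8 generations per day).
#' @param b_day,e_day Beginning and end days (defaults 0 and 3).
#' @param pseudo Pseudo-abundance replacing zeros (default 0.5).
#' @return Tibble of class `"pf_fitness"`: `mutant_id`, `condition`,
#'   `period_h`, `replicate`, `w`. Replicates missing either endpoint sample
#'   are skipped.
#' @export
fitness_table <- function(norm, samples, neutral_set, g = 24,
                          b_day = 0, e_day = 3, pseudo = 0.5) {
  stopifnot(inherits(norm, "pf_norm"))
  scaled <- norm$scaled
  wt <- artificial_wt(norm, neutral_set)
  wt_ab <- stats::setNames(wt$wt_abundance, wt$sample_id)
  pairs <- samples |>
    dplyr::filter(.data$day %in% c(b_day, e_day)) |>
    dplyr::mutate(role = ifelse(.data$day == b_day, "b", "e")) |>
    dplyr::select("condition", "period_h", "replicate", "role", "sample_id") |>
    tidyr::pivot_wider(names_from = "role", values_from = "sample_id") |>
    dplyr::filter(!is.na(.data$b), !is.na(.data$e))
  if (nrow(pairs) == 0)
    stop("no replicate has samples at both endpoint days", call. = FALSE)
  val <- function(s) {
    x <- scaled[[s]]
    ifelse(x <= 0, pseudo, x)
  }
  out <- purrr::pmap_dfr(pairs, function(condition, period_h, replicate, b, e) {
    tibble::tibble(
      mutant_id = scaled$mutant_id,
      condition = condition, period_h = period_h, replicate = replicate,
      w = fitness_w(val(b), val(e),
                    max(wt_ab[[b]], pseudo), max(wt_ab[[e]], pseudo), g = g)
    )
  })
  class(out) <- c("pf_fitness", class(out))
  out
}

#' Observed vs. time-average fitness per mutant and periodic condition
#'
#' Summarizes replicate fitness values per mutant and condition (mean), then
#' computes `w_expected` from the steady-condition means and the schedule's
#' time fractions at the endpoint day, and the inhomogeneity ratio `dev`.
#'
#' @param fit A [fitness_table()] tibble.
#' @param design A [design_table()] tibble (for `f_N`, `f_S` at `e_day`).
#' @param e_day Endpoint day whose time fractions apply (default 3).
#' @param steady_N,steady_S Labels of the steady conditions (defaults
#'   `"N"`, `"S"`).
#' @return Tibble: `mutant_id`, `condition`, `period_h`, `w_obs`, `w_N`,
#'   `w_S`, `f_N`, `w_exp`, `dev` — one row per mutant x periodic condition.
#' @export
dev_table <- function(fit, design, e_day = 3, steady_N = "N", steady_S = "S") {
  means <- fit |>
    dplyr::group_by(.data$mutant_id, .data$condition, .data$period_h) |>
    dplyr::summarise(w = mean(.data$w), .groups = "drop")
  steady <- means |>
    dplyr::filter(.data$condition %in% c(steady_N, steady_S)) |>
    dplyr::mutate(which = ifelse(.data$condition == steady_N, "w_N", "w_S")) |>
    dplyr::select("mutant_id", "which", "w") |>
    tidyr::pivot_wider(names_from = "which", values_from = "w")
  fr <- design |>
    dplyr::filter(.data$day == e_day) |>
    dplyr::select("condition", "f_N", "f_S")
  means |>
    dplyr::filter(.data$period_h > 0) |>
    dplyr::rename(w_obs = "w") |>
    dplyr::left_join(steady, by = "mutant_id") |>
    dplyr::left_join(fr, by = "condition") |>
    dplyr::mutate(w_exp = expected_fitness(.data$w_N, .data$w_S,
                                           .data$f_N, .data$f_S),
                  dev = inhomogeneity_dev(.data$w_obs, .data$w_exp))
}
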