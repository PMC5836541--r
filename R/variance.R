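#' Genetic-variance decomposition of pooled fitness
#'
#' Decomposes the variance of replicate fitness measurements within one
#' condition into `V_T` (total variance around the global mean), `V_E`
#' (within-mutant replicate variance, the non-genetic component) and
#' `V_G = V_T - V_E` (the genetic variance in fitness, proxying the diversity
#' of selection coefficients in the pool). Both components use population
#' divisors (1 / total observations, no Bessel correction); ragged replicate
#' counts are supported. The 95% confidence interval of `V_G` is obtained by
#' resampling mutants with replacement.
#'
#' @param w_reps Tibble with columns `mutant_id` and `w` (one row per
#'   replicate measurement) for a single condition; a [fitness_table()]
#'   restricted to one condition works directly.
#' @param n_bootstrap Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95, percentile interval).
#' @return Object of class `"pf_vardecomp"` with elements `V_T`, `V_E`,
#'   `V_G`, `ci` (length-2 vector), `n_bootstrap`, `n_mutants`,
#'   `n_observations`.
#' @export
genetic_variance <- function(w_reps, n_bootstrap = 1000, seed = 1L,
                             conf_level = 0.95) {
  stopifnot(all(c("mutant_id", "w") %in% names(w_reps)))
  w_list <- split(w_reps$w, w_reps$mutant_id)
  w_list <- w_list[vapply(w_list, length, integer(1)) >= 2]
  n_mut <- length(w_list)
  if (n_mut < 2)
    stop("need >= 2 mutants with >= 2 replicates each", call. = FALSE)
  comp <- vardecomp_components(w_list)
  # per-mutant sufficient statistics make the bootstrap O(n) per resample
  n_i <- lengths(w_list)
  m_i <- vapply(w_list, mean, numeric(1))
  ss_i <- vapply(w_list, function(x) sum((x - mean(x))^2), numeric(1))
  set.seed(seed)
  boot <- vapply(seq_len(n_bootstrap), function(b) {
    idx <- sample.int(n_mut, n_mut, replace = TRUE)
    n_tot <- sum(n_i[idx])
    gbar <- sum(n_i[idx] * m_i[idx]) / n_tot
    V_T <- (sum(ss_i[idx]) + sum(n_i[idx] * (m_i[idx] - gbar)^2)) / n_tot
    V_E <- sum(ss_i[idx]) / n_tot
    V_T - V_E
  }, numeric(1))
  a <- (1 - conf_level) / 2
  structure(
    list(V_T = comp[["V_T"]], V_E = comp[["V_E"]],
         V_G = comp[["V_T"]] - comp[["V_E"]],
         ci = unname(stats::quantile(boot, c(a, 1 - a))),
         conf_level = conf_level,
         n_bootstrap = n_bootstrap, n_mutants = n_mut,
         n_observations = sum(lengths(w_list))),
    class = "pf_vardecomp"
  )
}

vardecomp_components <- function(w_list) {
  all_w <- unlist(w_list, use.names = FALSE)
  n_obs <- length(all_w)
  gbar <- mean(all_w)
  V_T <- sum((all_w - gbar)^2) / n_obs
  V_E <- sum(vapply(w_list, function(x) sum((x - mean(x))^2), numeric(1))) / n_obs
  c(V_T = V_T, V_E = V_E)
}

#' @export
print.pf_vardecomp <- function(x, ...) {
  cat(sprintf(paste0("<pf_vardecomp> V_T = %.3g, V_E = %.3g, V_G = %.3g ",
                     "[%.3g, %.3g] (%d mutants, %d bootstraps)\n"),
              x$V_T, x$V_E, x$V_G, x$ci[1], x$ci[2], x$n_mutants,
              x$n_bootstrap))
  invisible(x)
}
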