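#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a variance decomposition
#' @param x A [genetic_variance()] object.
#' @param ... Unused.
#' @return Tibble with one row per variance component (`V_T`, `V_E`, `V_G`)
#'   and bootstrap confidence limits for `V_G`.
#' @method tidy pf_vardecomp
#' @export
tidy.pf_vardecomp <- function(x, ...) {
  tibble::tibble(
    component = c("V_T", "V_E", "V_G"),
    estimate = c(x$V_T, x$V_E, x$V_G),
    conf.low = c(NA, NA, x$ci[1]),
    conf.high = c(NA, NA, x$ci[2])
  )
}

#' @rdname tidy.pf_vardecomp
#' @method glance pf_vardecomp
#' @export
glance.pf_vardecomp <- function(x, ...) {
  tibble::tibble(V_T = x$V_T, V_E = x$V_E, V_G = x$V_G,
                 conf.low = x$ci[1], conf.high = x$ci[2],
                 conf.level = x$conf_level,
                 n_mutants = x$n_mutants, n_observations = x$n_observations,
                 n_bootstrap = x$n_bootstrap)
}

#' Tidy per-mutant inhomogeneity GLM fits
#' @param x A [fit_inhomogeneity_glms()] tibble.
#' @param ... Unused.
#' @return Long tibble: one row per mutant x coefficient with estimate,
#'   standard error and (for the change term) the p-value.
#' @method tidy pf_inhom
#' @export
tidy.pf_inhom <- function(x, ...) {
  x |>
    dplyr::select("mutant_id", "beta1", "beta2", "beta3",
                  "se1", "se2", "se3", "p_beta3", "converged") |>
    tidyr::pivot_longer(cols = c("beta1", "beta2", "beta3"),
                        names_to = "term", values_to = "estimate") |>
    dplyr::mutate(
      std.error = dplyr::case_when(term == "beta1" ~ .data$se1,
                                   term == "beta2" ~ .data$se2,
                                   TRUE ~ .data$se3),
      term = dplyr::recode(term, beta1 = "t_N", beta2 = "t_S",
                           beta3 = "n_changes"),
      p.value = ifelse(.data$term == "n_changes", .data$p_beta3, NA_real_)
    ) |>
    dplyr::select("mutant_id", "term", "estimate", "std.error", "p.value",
                  "converged")
}

#' @rdname tidy.pf_inhom
#' @method glance pf_inhom
#' @export
glance.pf_inhom <- function(x, ...) {
  tibble::tibble(
    n_mutants = nrow(x),
    n_converged = sum(x$converged),
    period_h = attr(x, "period_h") %||% NA_real_,
    median_alpha = stats::median(x$alpha, na.rm = TRUE)
  )
}

#' Tidy antagonistic-pleiotropy calls
#' @param x An [ap_calls()] tibble.
#' @param ... Unused.
#' @method tidy pf_ap
#' @export
tidy.pf_ap <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.pf_ap
#' @method glance pf_ap
#' @export
glance.pf_ap <- function(x, ...) {
  tibble::tibble(n_mutants = nrow(x), n_AP = sum(x$is_AP),
                 mean_magnitude_AP = mean(x$magnitude[x$is_AP]))
}
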