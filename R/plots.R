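#' Plot the (w_N, w_S) cloud with the AP outlier ellipse
#'
#' Scatter of all paired steady-condition fitness observations, the fitted
#' bivariate Gaussian's Mahalanobis-2 ellipse, and AP-called mutants
#' highlighted.
#'
#' @param object An [ap_calls()] result.
#' @param cutoff Ellipse radius in Mahalanobis units (default 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pf_ap
#' @export
autoplot.pf_ap <- function(object, cutoff = 2, ...) {
  pairs <- attr(object, "pairs")
  model <- attr(object, "model")
  pairs$is_AP <- pairs$mutant_id %in% object$mutant_id[object$is_AP]
  th <- seq(0, 2 * pi, length.out = 200)
  ell <- t(model$mean + cutoff * chol(model$cov) %*% rbind(cos(th), sin(th)))
  ell <- tibble::tibble(w_N = ell[, 1], w_S = ell[, 2])
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$w_N, y = .data$w_S)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_AP), alpha = 0.6,
                        size = 1) +
    ggplot2::geom_path(data = ell, linetype = 2) +
    ggplot2::geom_hline(yintercept = 1, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linewidth = 0.2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "fitness in steady N", y = "fitness in steady S",
                  colour = "AP call")
}

#' Plot the beta3 p-value distribution of the inhomogeneity GLM
#'
#' Histogram of the environment-change-term p-values across mutants; under
#' full homogenization this distribution is uniform.
#'
#' @param object A [fit_inhomogeneity_glms()] result.
#' @param bins Histogram bins (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pf_inhom
#' @export
autoplot.pf_inhom <- function(object, bins = 20, ...) {
  df <- tibble::tibble(p = object$p_beta3[object$converged])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_hline(yintercept = nrow(df) / bins, linetype = 2) +
    ggplot2::labs(x = "p-value (environment-change term)", y = "mutants")
}

#' Plot a variance decomposition with its bootstrap interval
#'
#' @param object A [genetic_variance()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pf_vardecomp
#' @export
autoplot.pf_vardecomp <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "variance in fitness")
}

#' Plot an FL1 distribution with its automatic GFP threshold
#'
#' @param object A [find_gfp_threshold()] object.
#' @param fl1 The FL1 values the threshold was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pf_gfp_threshold
#' @export
autoplot.pf_gfp_threshold <- function(object, fl1, ...) {
  df <- tibble::tibble(FL1 = fl1)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$FL1)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::labs(x = "FL1 (instrument units)", y = "density")
  if (!object$unimodal)
    gg <- gg + ggplot2::geom_vline(xintercept = object$threshold,
                                   colour = "firebrick", linetype = 2)
  gg
}
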