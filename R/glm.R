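#' Per-sample GLM covariates from the sample sheet
#'
#' Joins each sample to its schedule-derived exposure times and change count.
#' Exposure times are returned in days (`t_N_d`, `t_S_d`), the scale on which
#' the GLM coefficients are reported; `n_changes` is the number of medium
#' switches since day 0.
#'
#' @param samples Sample sheet (`sample_id`, `condition`, `period_h`, `day`,
#'   `replicate`).
#' @param first_condition Starting medium of periodic schedules (default
#'   `"S"`).
#' @param transfer_interval_h Transfer grid (default 3 h).
#' @return Tibble: sample sheet columns plus `t_N_d`, `t_S_d`, `n_changes`.
#' @export
glm_design <- function(samples, first_condition = "S", transfer_interval_h = 3) {
  conds <- dplyr::distinct(samples, .data$condition, .data$period_h)
  total_h <- max(samples$day) * 24
  des <- design_table(conds, days = sort(unique(samples$day)),
                      first_condition = first_condition,
                      transfer_interval_h = transfer_interval_h,
                      total_h = max(total_h, 24))
  samples |>
    dplyr::left_join(des |>
                       dplyr::select("condition", "day", "t_N", "t_S",
                                     "n_changes"),
                     by = c("condition", "day")) |>
    dplyr::mutate(t_N_d = .data$t_N / 24, t_S_d = .data$t_S / 24) |>
    dplyr::select(-"t_N", -"t_S")
}

#' Negative-binomial GLM for one mutant's count time course
#'
#' Fits `log lambda = offset_c + beta1 * t_N + beta2 * t_S +
#' beta3 * n_changes` to the mutant's normalized (size-factor-scaled,
#' rounded) counts across samples, with a negative-binomial error whose
#' dispersion alpha is estimated by alternating maximum likelihood with the
#' coefficients (`MASS::glm.nb`). The offset is the log median of the
#' mutant's day-0 normalized counts, entered with a fixed coefficient of 1
#' (not estimated). Because every population is initialized identically
#' before day 0 (the conditions only diverge afterwards), the default pools
#' all day-0 samples into a single per-mutant offset; this makes the
#' offset's sampling error a shared intercept shift that cancels in the
#' balanced change-term contrast, keeping the beta3 test calibrated.
#' `offset_mode = "per_condition"` instead uses the day-0 median within each
#' condition, for designs whose day-0 populations genuinely differ (e.g.
#' imputed day-0 columns). Under fitness homogenization the
#' environment-change term vanishes, so `beta3 = 0` is the null hypothesis of
#' interest; its p-value is a Wald test by default, or a likelihood-ratio
#' test with `test = "lrt"`.
#'
#' Maximum-likelihood NB dispersion estimates are biased low in small
#' samples, which inflates Wald z statistics; both tests therefore apply a
#' quasi-likelihood moderation, rescaling by the Pearson residual dispersion
#' and referring to a t (respectively F) distribution on the residual
#' degrees of freedom. Reported standard errors and the coefficient
#' covariance include the same rescaling.
#'
#' @param y Non-negative counts, one per row of `design` (rounded
#'   internally).
#' @param design Covariates from [glm_design()] for the same samples:
#'   columns `condition`, `day`, `t_N_d`, `t_S_d`, `n_changes`.
#' @param test `"wald"` (default) or `"lrt"` for the beta3 p-value.
#' @param offset_mode `"pooled"` (default) or `"per_condition"`.
#' @param pseudo Pseudo-count replacing a zero day-0 median offset.
#' @return One-row tibble: `beta1`, `beta2`, `beta3`, `se1`..`se3`, `alpha`,
#'   `loglik`, `p_beta3`, `converged`, plus list-columns `offsets` (named
#'   per-condition offsets, log scale) and `vcov`.
#' @export
fit_mutant_glm <- function(y, design, test = c("wald", "lrt"),
                           offset_mode = c("pooled", "per_condition"),
                           pseudo = 0.5) {
  test <- match.arg(test)
  offset_mode <- match.arg(offset_mode)
  stopifnot(length(y) == nrow(design))
  if (!any(design$day == 0))
    stop("day-0 samples are required to anchor the offsets", call. = FALSE)
  y <- round(y)
  conds <- sort(unique(as.character(design$condition)))
  med0 <- if (offset_mode == "pooled") {
    stats::setNames(rep(stats::median(y[design$day == 0]), length(conds)),
                    conds)
  } else {
    tapply(y[design$day == 0], design$condition[design$day == 0],
           stats::median)[conds]
  }
  med0[med0 <= 0] <- pseudo
  off <- log(med0)[as.character(design$condition)]
  dat <- data.frame(y = y, t_N = design$t_N_d, t_S = design$t_S_d,
                    n_changes = design$n_changes, off = as.numeric(off))
  na_row <- tibble::tibble(beta1 = NA_real_, beta2 = NA_real_, beta3 = NA_real_,
                           se1 = NA_real_, se2 = NA_real_, se3 = NA_real_,
                           alpha = NA_real_, loglik = NA_real_,
                           p_beta3 = NA_real_, converged = FALSE,
                           offsets = list(log(med0)), vcov = list(NULL))
  fit <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(y ~ 0 + t_N + t_S + n_changes + offset(off), data = dat),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (is.null(fit)) {
    # glm.nb diverges when the data are under-dispersed (theta -> Inf);
    # the Poisson limit of the NB model is then the correct fit
    fit <- tryCatch(
      suppressWarnings(
        stats::glm(y ~ 0 + t_N + t_S + n_changes + offset(off),
                   family = stats::poisson(), data = dat)),
      error = function(e) NULL)
    if (!is.null(fit)) fit$theta <- 1e8
  }
  if (is.null(fit)) return(na_row)
  sm <- summary(fit)
  co <- sm$coefficients
  if (nrow(co) < 3 || any(!is.finite(co[, 2]))) return(na_row)
  alpha <- 1 / fit$theta
  df_res <- fit$df.residual
  phi <- max(sum(stats::residuals(fit, "pearson")^2) / df_res, 1e-6)
  p <- if (test == "wald") {
    z <- co["n_changes", "z value"] / sqrt(phi)
    2 * stats::pt(-abs(z), df = df_res)
  } else {
    fit0 <- tryCatch(
      withCallingHandlers(
        MASS::glm.nb(y ~ 0 + t_N + t_S + offset(off), data = dat),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(fit0)) NA_real_ else
      stats::pf(2 * (stats::logLik(fit) - stats::logLik(fit0)) / phi,
                1, df_res, lower.tail = FALSE)
  }
  tibble::tibble(
    beta1 = co["t_N", 1], beta2 = co["t_S", 1], beta3 = co["n_changes", 1],
    se1 = co["t_N", 2] * sqrt(phi), se2 = co["t_S", 2] * sqrt(phi),
    se3 = co["n_changes", 2] * sqrt(phi),
    alpha = max(alpha, 1e-8), loglik = as.numeric(stats::logLik(fit)),
    p_beta3 = as.numeric(p), converged = isTRUE(fit$converged),
    offsets = list(log(med0)), vcov = list(stats::vcov(fit) * phi)
  )
}

#' Fit the inhomogeneity GLM for every mutant, one oscillating period
#'
#' Pools the samples of the two steady conditions with those of one periodic
#' condition (one model per oscillating period) and fits [fit_mutant_glm()]
#' to each mutant.
#'
#' @param norm A [normalize_counts()] object.
#' @param samples Sample sheet covering the pooled samples.
#' @param period_h Oscillation period of the periodic condition to test.
#' @param steady Labels of the steady conditions (default `c("N", "S")`).
#' @param mutants Optional subset of mutant ids (default all).
#' @param test,offset_mode,first_condition Passed through.
#' @return Tibble of class `"pf_inhom"`, one row per mutant (`mutant_id` +
#'   [fit_mutant_glm()] columns); the design used is kept in attribute
#'   `"design"`.
#' @export
fit_inhomogeneity_glms <- function(norm, samples, period_h,
                                   steady = c("N", "S"), mutants = NULL,
                                   test = "wald", offset_mode = "pooled",
                                   first_condition = "S") {
  stopifnot(inherits(norm, "pf_norm"))
  use <- samples |>
    dplyr::filter(.data$condition %in% steady | .data$period_h == !!period_h)
  if (!any(use$period_h == period_h))
    stop(sprintf("no samples with period %g h", period_h), call. = FALSE)
  des <- glm_design(use, first_condition = first_condition)
  scaled <- norm$scaled
  if (is.null(mutants)) mutants <- scaled$mutant_id
  ymat <- as.matrix(scaled[match(mutants, scaled$mutant_id), des$sample_id])
  fits <- purrr::map_dfr(seq_along(mutants), function(i) {
    fit_mutant_glm(ymat[i, ], des, test = test, offset_mode = offset_mode)
  })
  out <- dplyr::bind_cols(tibble::tibble(mutant_id = mutants), fits)
  attr(out, "design") <- des
  attr(out, "period_h") <- period_h
  class(out) <- c("pf_inhom", class(out))
  out
}

#' q-values controlling the false discovery rate
#'
#' Storey's q-values with the smoother-based estimate of the null proportion
#' pi0 (a cubic smoothing spline through `pi0(lambda) = mean(p > lambda) /
#' (1 - lambda)` evaluated at its right end). When the pi0 estimate is
#' unstable (outside (0, 1], or too few p-values to smooth) the function
#' falls back to Benjamini-Hochberg (pi0 = 1) with a message.
#'
#' @param p Vector of p-values.
#' @param method `"smoother"` (default) or `"BH"`.
#' @return Vector of q-values; the pi0 used is attached as attribute
#'   `"pi0"`.
#' @export
qvalues <- function(p, method = c("smoother", "BH")) {
  method <- match.arg(method)
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  ok <- !is.na(p)
  pv <- p[ok]
  n <- length(pv)
  pi0 <- 1
  if (method == "smoother") {
    lam <- seq(0.05, 0.95, by = 0.05)
    if (n >= 100) {
      pi0_lam <- vapply(lam, function(l) mean(pv > l) / (1 - l), numeric(1))
      sp <- try(stats::smooth.spline(lam, pi0_lam, df = 3), silent = TRUE)
      pi0 <- if (inherits(sp, "try-error")) NA_real_ else
        stats::predict(sp, x = max(lam))$y
    } else pi0 <- NA_real_
    if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) {
      message("pi0 estimate unstable; falling back to Benjamini-Hochberg (pi0 = 1)")
      pi0 <- 1
    }
  }
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * pmin(1, cummin(n / (n - seq_along(pv) + 1) * pv[o]))[ro]
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Call inhomogeneous mutants at a target FDR
#'
#' Converts the beta3 p-values of converged fits to q-values and returns the
#' mutants with `q <= fdr`. Unconverged fits are excluded from the FDR
#' calculation.
#'
#' @param fits A [fit_inhomogeneity_glms()] tibble.
#' @param fdr Target false discovery rate.
#' @param method q-value method, see [qvalues()].
#' @return Character vector of called mutant ids; the full q-value table is
#'   attached as attribute `"q_table"`.
#' @export
call_inhomogeneous <- function(fits, fdr, method = "smoother") {
  if (nrow(fits) == 0) stop("empty fit list", call. = FALSE)
  use <- fits[fits$converged & !is.na(fits$p_beta3), ]
  if (nrow(use) == 0) return(character(0))
  q <- qvalues(use$p_beta3, method = method)
  called <- use$mutant_id[q <= fdr]
  attr(called, "q_table") <- tibble::tibble(mutant_id = use$mutant_id,
                                            p_beta3 = use$p_beta3,
                                            q_beta3 = as.numeric(q))
  called
}

#' Predicted abundance trajectory of a fitted mutant GLM
#'
#' Evaluates `lambda = exp(offset_c + beta1 t_N + beta2 t_S +
#' beta3 n_changes)` per condition and day, with a delta-method standard
#' error from the coefficient covariance.
#'
#' @param fit One row of a [fit_inhomogeneity_glms()] result (or
#'   [fit_mutant_glm()] output) with `converged = TRUE`.
#' @param design Per-condition/day covariates: `condition`, `day`, `t_N_d`,
#'   `t_S_d`, `n_changes` (e.g. distinct rows of [glm_design()] output).
#' @return Tibble: `condition`, `day`, `lambda_hat`, `se`.
#' @export
glm_predicted_trajectory <- function(fit, design) {
  stopifnot(nrow(fit) == 1)
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  des <- dplyr::distinct(design, .data$condition, .data$day, .data$t_N_d,
                         .data$t_S_d, .data$n_changes)
  beta <- c(fit$beta1, fit$beta2, fit$beta3)
  V <- fit$vcov[[1]]
  off <- fit$offsets[[1]]
  X <- as.matrix(des[, c("t_N_d", "t_S_d", "n_changes")])
  eta <- as.numeric(off[as.character(des$condition)] + X %*% beta)
  lam <- exp(eta)
  se <- if (is.null(V)) NA_real_ else
    lam * sqrt(rowSums((X %*% V) * X))
  tibble::tibble(condition = des$condition, day = des$day,
                 lambda_hat = lam, se = se)
}
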