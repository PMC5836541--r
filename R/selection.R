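#' Pair replicate fitness observations across two steady conditions
#'
#' The steady-N condition contributes 3 replicate fitness values and steady S
#' contributes 4 (one N day-3 sample was lost); the extra observations on the
#' longer side are discarded uniformly at random and the remainder paired in
#' index order, giving `min(length(w_N), length(w_S))` independent (w_N, w_S)
#' observations per mutant.
#'
#' @param w_N,w_S Replicate fitness vectors for the two steady conditions.
#' @param seed Integer seed for the random discard.
#' @return Tibble: `w_N`, `w_S`, one row per pair; `NULL` (with a message)
#'   when either side has fewer than 2 values.
#' @export
pair_replicates <- function(w_N, w_S, seed = 1L) {
  if (length(w_N) < 2 || length(w_S) < 2) {
    message("fewer than 2 replicates on one side; mutant skipped")
    return(NULL)
  }
  set.seed(seed)
  k <- min(length(w_N), length(w_S))
  if (length(w_N) > k) w_N <- w_N[sort(sample.int(length(w_N), k))]
  if (length(w_S) > k) w_S <- w_S[sort(sample.int(length(w_S), k))]
  tibble::tibble(w_N = w_N, w_S = w_S)
}

#' Fit a bivariate Gaussian to all (w_N, w_S) observations
#'
#' Maximum-likelihood mean vector and covariance of the pooled cloud of
#' fitness pairs; outliers are points whose Mahalanobis distance from the
#' fitted model strictly exceeds `cutoff` ("two standard deviations away"
#' in covariance-scaled units). For a standard bivariate normal, the squared
#' distance is chi-squared with 2 df, so a fraction `exp(-2)` of about 13.5%
#' falls beyond distance 2.
#'
#' @param pairs Tibble/data frame with columns `w_N`, `w_S` (all mutants'
#'   observations pooled).
#' @return Object of class `"pf_bigauss"`: `mean` (length 2), `cov` (2x2).
#' @export
fit_bivariate_gaussian <- function(pairs) {
  X <- cbind(pairs$w_N, pairs$w_S)
  if (nrow(X) < 3) stop("need >= 3 observations", call. = FALSE)
  mu <- colMeans(X)
  S <- crossprod(sweep(X, 2, mu)) / nrow(X)  # ML covariance
  if (!is.finite(determinant(S)$modulus) || det(S) <= 0)
    stop("singular covariance; cannot fit bivariate Gaussian", call. = FALSE)
  structure(list(mean = stats::setNames(mu, c("w_N", "w_S")), cov = S),
            class = "pf_bigauss")
}

#' Mahalanobis distances under a fitted bivariate Gaussian
#' @param model A [fit_bivariate_gaussian()] object.
#' @param pairs Tibble with columns `w_N`, `w_S`.
#' @return Numeric vector of distances (not squared).
#' @export
mahalanobis_dist <- function(model, pairs) {
  unname(sqrt(stats::mahalanobis(cbind(pairs$w_N, pairs$w_S), model$mean,
                                 model$cov)))
}

#' Antagonistic-pleiotropy call for one mutant
#'
#' An observation (one (w_N, w_S) pair) supports AP when (1) the fitness
#' values point in opposite directions across the two media
#' (`(w_N > 1 & w_S < 1) | (w_N < 1 & w_S > 1)`) and (2) the pair deviates
#' from the bulk of all observed pairs, i.e. its Mahalanobis distance under
#' the fitted bivariate Gaussian strictly exceeds `cutoff`. The mutant is
#' called AP only if every pair supports AP. AP magnitude is `w_N / w_S`.
#'
#' @param pairs [pair_replicates()] output for the mutant.
#' @param model Bivariate Gaussian fitted to all mutants' pairs.
#' @param cutoff Mahalanobis cutoff (default 2; strictly greater is an
#'   outlier).
#' @return One-row tibble: `is_AP`, `n_support`, `n_pairs`,
#'   `magnitude` (mean of per-pair `w_N / w_S`), `max_mahalanobis`.
#' @export
call_AP <- function(pairs, model, cutoff = 2) {
  d <- mahalanobis_dist(model, pairs)
  sign_ok <- (pairs$w_N > 1 & pairs$w_S < 1) | (pairs$w_N < 1 & pairs$w_S > 1)
  support <- sign_ok & d > cutoff
  tibble::tibble(is_AP = all(support), n_support = sum(support),
                 n_pairs = nrow(pairs),
                 magnitude = mean(pairs$w_N / pairs$w_S),
                 max_mahalanobis = max(d))
}

#' Antagonistic-pleiotropy calls for every mutant
#'
#' Pairs each mutant's steady-condition replicates, fits the bivariate
#' Gaussian to the pooled pairs, and applies [call_AP()] per mutant.
#'
#' @param fit A [fitness_table()] tibble containing the two steady
#'   conditions.
#' @param steady_N,steady_S Steady condition labels.
#' @param cutoff Mahalanobis cutoff (default 2).
#' @param seed Seed for the replicate discard in [pair_replicates()].
#' @return Tibble of class `"pf_ap"`: `mutant_id` + [call_AP()] columns; the
#'   fitted Gaussian in attribute `"model"`, the paired observations in
#'   attribute `"pairs"`.
#' @export
ap_calls <- function(fit, steady_N = "N", steady_S = "S", cutoff = 2,
                     seed = 1L) {
  wN <- split(fit$w[fit$condition == steady_N],
              fit$mutant_id[fit$condition == steady_N])
  wS <- split(fit$w[fit$condition == steady_S],
              fit$mutant_id[fit$condition == steady_S])
  ids <- intersect(names(wN), names(wS))
  pair_list <- purrr::imap(stats::setNames(ids, ids), function(id, nm) {
    suppressMessages(pair_replicates(wN[[id]], wS[[id]],
                                     seed = seed + match(id, ids)))
  })
  pair_list <- purrr::compact(pair_list)
  if (length(pair_list) == 0) stop("no mutant has enough replicates", call. = FALSE)
  all_pairs <- dplyr::bind_rows(pair_list, .id = "mutant_id")
  model <- fit_bivariate_gaussian(all_pairs)
  out <- purrr::map_dfr(pair_list, call_AP, model = model, cutoff = cutoff,
                        .id = "mutant_id")
  attr(out, "model") <- model
  attr(out, "pairs") <- all_pairs
  class(out) <- c("pf_ap", class(out))
  out
}

#' Permutation null for the AP call count
#'
#' Reassigns the observed (w_N, w_S) pairs to mutants at random (preserving
#' the per-mutant pair counts), refits nothing (the bulk Gaussian is
#' permutation-invariant) and reruns AP calling, returning the mean AP count
#' across permutations — the number of deletions expected to have all pairs
#' supporting AP by chance.
#'
#' @param calls An [ap_calls()] result (uses its `"pairs"` and `"model"`
#'   attributes).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param cutoff Mahalanobis cutoff (default 2).
#' @return List: `expected` (mean permuted AP count), `counts` (per-
#'   permutation counts), `observed` (the real AP count).
#' @export
permutation_null_AP <- function(calls, n_perm = 1000, seed = 1L, cutoff = 2) {
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  pairs <- attr(calls, "pairs")
  model <- attr(calls, "model")
  d <- mahalanobis_dist(model, pairs)
  support <- ((pairs$w_N > 1 & pairs$w_S < 1) |
                (pairs$w_N < 1 & pairs$w_S > 1)) & d > cutoff
  sizes <- table(pairs$mutant_id)
  set.seed(seed)
  equal_sizes <- length(unique(sizes)) == 1L
  grp <- rep(seq_along(sizes), sizes)
  counts <- vapply(seq_len(n_perm), function(b) {
    perm <- sample(support)
    if (equal_sizes) {
      sum(rowSums(matrix(perm, nrow = length(sizes), byrow = TRUE)) ==
            sizes[1])
    } else {
      sum(tapply(perm, grp, all))
    }
  }, numeric(1))
  list(expected = mean(counts), counts = counts,
       observed = sum(calls$is_AP))
}

#' Direction of selection per period and overall class
#'
#' Per period, selection is positive if `mean(w) - sd(w) > 1`, negative if
#' `mean(w) + sd(w) < 1`, and ambiguous otherwise. A mutant is classified
#' `"unclear"` when ambiguous at four or five of the five periods,
#' `"always_positive"`/`"always_negative"` when all its unambiguous
#' directions agree, and `"period_dependent"` when they differ.
#'
#' @param w_reps Tibble with columns `period_h` (or `condition`) and `w`,
#'   replicate fitness values in the periodic regimes for one mutant.
#' @return List: `per_period` (tibble `period_h`, `mean`, `sd`, `direction`)
#'   and `class_label`.
#' @export
classify_direction <- function(w_reps) {
  key <- if ("period_h" %in% names(w_reps)) "period_h" else "condition"
  per <- w_reps |>
    dplyr::group_by(.data[[key]]) |>
    dplyr::summarise(mean = mean(.data$w), sd = stats::sd(.data$w),
                     .groups = "drop") |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$mean - .data$sd > 1 ~ "positive",
      .data$mean + .data$sd < 1 ~ "negative",
      TRUE ~ "ambiguous"))
  n_periods <- nrow(per)
  n_ambig <- sum(per$direction == "ambiguous")
  unambig <- unique(per$direction[per$direction != "ambiguous"])
  label <- if (n_ambig >= n_periods - 1) "unclear"
  else if (identical(unambig, "positive")) "always_positive"
  else if (identical(unambig, "negative")) "always_negative"
  else "period_dependent"
  list(per_period = per, class_label = label)
}

#' Transgressive-fitness call for one mutant
#'
#' A mutant is transgressive when at least `min_support` of its replicate
#' fitness values in the oscillating regime lie beyond the steady-condition
#' envelope: all above `max(mean_N + sd_N, mean_S + sd_S)` (`"high"`) or all
#' below `min(mean_N - sd_N, mean_S - sd_S)` (`"low"`).
#'
#' @param w_NS Replicate fitness values in the oscillating condition.
#' @param w_N_stats,w_S_stats Length-2 vectors `c(mean, sd)` of the steady-
#'   condition fitness values.
#' @param min_support Minimum number of supporting replicates (default 3 of
#'   4).
#' @return One-row tibble: `direction` (`"high"`, `"low"`, `"none"`),
#'   `n_supporting`, `upper`, `lower` (the envelope).
#' @export
call_transgressive <- function(w_NS, w_N_stats, w_S_stats, min_support = 3) {
  upper <- max(w_N_stats[1] + w_N_stats[2], w_S_stats[1] + w_S_stats[2])
  lower <- min(w_N_stats[1] - w_N_stats[2], w_S_stats[1] - w_S_stats[2])
  if (length(w_NS) < min_support) {
    message("fewer than ", min_support, " oscillating replicates; no call")
    return(tibble::tibble(direction = "none", n_supporting = 0L,
                          upper = upper, lower = lower))
  }
  n_high <- sum(w_NS > upper)
  n_low <- sum(w_NS < lower)
  direction <- if (n_high >= min_support) "high"
  else if (n_low >= min_support) "low"
  else "none"
  tibble::tibble(direction = direction,
                 n_supporting = max(n_high, n_low),
                 upper = upper, lower = lower)
}

#' Transgressive-fitness calls for every mutant
#'
#' @param fit A [fitness_table()] tibble.
#' @param osc_condition Label of the oscillating condition to test.
#' @param steady_N,steady_S Steady condition labels.
#' @param min_support Minimum supporting replicates (default 3).
#' @return Tibble of class `"pf_transgressive"`: `mutant_id` +
#'   [call_transgressive()] columns.
#' @export
transgressive_calls <- function(fit, osc_condition, steady_N = "N",
                                steady_S = "S", min_support = 3) {
  stats_of <- function(cond) {
    fit |>
      dplyr::filter(.data$condition == cond) |>
      dplyr::group_by(.data$mutant_id) |>
      dplyr::summarise(m = mean(.data$w), s = stats::sd(.data$w),
                       .groups = "drop")
  }
  sN <- stats_of(steady_N); sS <- stats_of(steady_S)
  wNS <- split(fit$w[fit$condition == osc_condition],
               fit$mutant_id[fit$condition == osc_condition])
  ids <- Reduce(intersect, list(names(wNS), sN$mutant_id, sS$mutant_id))
  out <- purrr::map_dfr(stats::setNames(ids, ids), function(id) {
    suppressMessages(call_transgressive(
      wNS[[id]],
      unlist(sN[sN$mutant_id == id, c("m", "s")]),
      unlist(sS[sS$mutant_id == id, c("m", "s")]),
      min_support = min_support))
  }, .id = "mutant_id")
  attr(out, "w_NS") <- wNS[ids]
  attr(out, "envelopes") <- out[, c("mutant_id", "upper", "lower")]
  class(out) <- c("pf_transgressive", class(out))
  out
}

#' Permutation null for the transgressive call count
#'
#' Reassigns the oscillating-condition replicate observations to random
#' mutants (preserving per-mutant replicate counts; each mutant keeps its own
#' steady-condition envelope) and reruns transgressivity calling.
#'
#' @param calls A [transgressive_calls()] result.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param min_support Minimum supporting replicates (default 3).
#' @return List: `expected`, `counts`, `observed`.
#' @export
permutation_null_transgressivity <- function(calls, n_perm = 1000, seed = 1L,
                                             min_support = 3) {
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  w_NS <- attr(calls, "w_NS")
  sizes <- lengths(w_NS)
  pool <- unlist(w_NS, use.names = FALSE)
  upper <- calls$upper
  lower <- calls$lower
  set.seed(seed)
  equal_sizes <- length(unique(sizes)) == 1L && sizes[1] >= min_support
  counts <- vapply(seq_len(n_perm), function(b) {
    perm <- sample(pool)
    if (equal_sizes) {
      m <- matrix(perm, nrow = length(sizes), byrow = TRUE)
      sum(rowSums(m > upper) >= min_support |
            rowSums(m < lower) >= min_support)
    } else {
      ends <- cumsum(sizes)
      starts <- ends - sizes + 1L
      n_call <- 0L
      for (i in seq_along(sizes)) {
        if (sizes[i] < min_support) next
        x <- perm[starts[i]:ends[i]]
        if (sum(x > upper[i]) >= min_support ||
            sum(x < lower[i]) >= min_support) n_call <- n_call + 1L
      }
      n_call
    }
  }, numeric(1))
  list(expected = mean(counts), counts = counts,
       observed = sum(calls$direction != "none"))
}
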