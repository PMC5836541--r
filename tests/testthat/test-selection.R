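ap_fixture <- function(n_bulk = 400, n_ap = 20, bulk_sd = 0.02, rep_sd = 0.01,
                       seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("bulk%04d", seq_len(n_bulk)),
           sprintf("ap%03d", seq_len(n_ap)))
  center_N <- c(rnorm(n_bulk, 1, bulk_sd), rep(1.1, n_ap))
  center_S <- c(rnorm(n_bulk, 1, bulk_sd), rep(0.9, n_ap))
  n <- length(ids)
  dplyr::bind_rows(
    tibble::tibble(mutant_id = rep(ids, each = 3), condition = "N",
                   period_h = 0, replicate = rep(1:3, n),
                   w = rep(center_N, each = 3) + rnorm(3 * n, 0, rep_sd)),
    tibble::tibble(mutant_id = rep(ids, each = 4), condition = "S",
                   period_h = 0, replicate = rep(1:4, n),
                   w = rep(center_S, each = 4) + rnorm(4 * n, 0, rep_sd))
  )
}

test_that("replicate pairing is seeded, fair and skips sparse mutants", {
  w_N <- c(1.0, 1.1, 1.2)
  w_S <- c(0.9, 0.8, 0.7, 0.6)
  p1 <- pair_replicates(w_N, w_S, seed = 42)
  p2 <- pair_replicates(w_N, w_S, seed = 42)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 3)
  # identical w_S values: pairing-invariant
  pc <- pair_replicates(w_N, rep(0.8, 4), seed = 7)
  expect_equal(pc$w_S, rep(0.8, 3))
  # each w_S discarded ~25% of the time over many seeds
  disc <- vapply(1:2000, function(s) {
    setdiff(w_S, pair_replicates(w_N, w_S, seed = s)$w_S)
  }, numeric(1))
  frac <- table(disc) / 2000
  expect_true(all(abs(frac - 0.25) < 0.04))
  expect_message(expect_null(pair_replicates(1, w_S)), "skipped")
})

test_that("the bivariate Gaussian outlier rate matches the chi-square tail", {
  set.seed(1)
  pairs <- tibble::tibble(w_N = rnorm(10000), w_S = rnorm(10000))
  model <- fit_bivariate_gaussian(pairs)
  d <- mahalanobis_dist(model, pairs)
  expect_lt(abs(mean(d > 2) - exp(-2)), 0.01)
  # a point at the mean has distance 0
  at_mean <- tibble::tibble(w_N = model$mean[1], w_S = model$mean[2])
  expect_equal(mahalanobis_dist(model, at_mean), 0, tolerance = 1e-8)
  expect_error(fit_bivariate_gaussian(pairs[1:2, ]), ">= 3")
})

test_that("the distance-2 boundary is not an outlier (strict inequality)", {
  model <- structure(list(mean = c(w_N = 1, w_S = 1), cov = diag(2)),
                     class = "pf_bigauss")
  boundary <- tibble::tibble(w_N = c(3, 1.5), w_S = c(1, 0.5))
  d <- mahalanobis_dist(model, boundary)
  expect_equal(d[1], 2)
  call <- call_AP(boundary, model)
  expect_false(call$is_AP)  # distance exactly 2 never supports AP
})

test_that("AP requires opposite signs and bulk deviation in all pairs", {
  model <- structure(list(mean = c(w_N = 1, w_S = 1),
                          cov = diag(2) * 0.02^2),
                     class = "pf_bigauss")
  good <- tibble::tibble(w_N = rep(1.1, 3), w_S = rep(0.9, 3))
  call <- call_AP(good, model)
  expect_true(call$is_AP)
  expect_equal(call$magnitude, 1.1 / 0.9)
  # both advantages: sign condition fails
  both_up <- tibble::tibble(w_N = c(1.1, 1.1, 1.2), w_S = c(0.9, 0.9, 1.1))
  expect_false(call_AP(both_up, model)$is_AP)
  # inside the 2-SD ellipse: condition (2) fails
  inside <- tibble::tibble(w_N = rep(1.01, 3), w_S = rep(0.99, 3))
  expect_false(call_AP(inside, model)$is_AP)
})

test_that("planted AP mutants are detected and the null expects few", {
  fit <- ap_fixture(seed = 2)
  calls <- ap_calls(fit, seed = 3)
  planted <- grepl("^ap", calls$mutant_id)
  expect_gte(mean(calls$is_AP[planted]), 0.95)
  expect_lte(sum(calls$is_AP[!planted]), 2)
  null <- permutation_null_AP(calls, n_perm = 200, seed = 4)
  expect_lt(null$expected, 0.05 * sum(planted))
  expect_equal(null$observed, sum(calls$is_AP))
})

test_that("permuted expectation matches observed count on exchangeable data", {
  # exchangeable: no per-mutant structure (all centers equal, noise i.i.d.)
  fit <- ap_fixture(n_bulk = 300, n_ap = 0, bulk_sd = 0, rep_sd = 0.03,
                    seed = 5)
  calls <- ap_calls(fit, seed = 6)
  null <- permutation_null_AP(calls, n_perm = 300, seed = 7)
  se <- stats::sd(null$counts) / sqrt(length(null$counts))
  spread <- max(2 * stats::sd(null$counts), 2)
  expect_lte(abs(null$expected - null$observed), spread)
  expect_equal(permutation_null_AP(calls, n_perm = 1, seed = 9)$expected,
               permutation_null_AP(calls, n_perm = 1, seed = 9)$expected)
})

test_that("direction classification follows the mean +/- sd rule", {
  one <- function(m, s) tibble::tibble(period_h = 6, w = c(m - s, m + s))
  expect_equal(classify_direction(one(1.05, 0.01))$per_period$direction,
               "positive")
  expect_equal(classify_direction(one(1.05, 0.10))$per_period$direction,
               "ambiguous")
  expect_equal(classify_direction(one(0.9, 0.05))$per_period$direction,
               "negative")
  # period pattern (pos, pos, ambig, neg, ambig) -> period_dependent
  set.seed(8)
  d <- dplyr::bind_rows(
    tibble::tibble(period_h = 6, w = rnorm(4, 1.10, 0.01)),
    tibble::tibble(period_h = 12, w = rnorm(4, 1.10, 0.01)),
    tibble::tibble(period_h = 18, w = rnorm(4, 1.00, 0.30)),
    tibble::tibble(period_h = 24, w = rnorm(4, 0.90, 0.01)),
    tibble::tibble(period_h = 42, w = rnorm(4, 1.00, 0.30)))
  expect_equal(classify_direction(d)$class_label, "period_dependent")
  # ambiguous nearly everywhere -> unclear
  d2 <- d
  d2$w <- rnorm(20, 1, 0.5)
  expect_equal(classify_direction(d2)$class_label, "unclear")
})

test_that("transgressivity applies the 3-of-4 envelope rule", {
  # envelope upper bound = max(1.00, 0.95) = 1.00 with zero SDs
  call <- call_transgressive(c(1.02, 1.03, 1.02, 0.99),
                             c(1.00, 0), c(0.95, 0))
  expect_equal(call$direction, "high")
  expect_equal(call$n_supporting, 3L)
  inside <- call_transgressive(c(0.99, 0.98, 0.97, 0.99),
                               c(1.00, 0), c(0.95, 0))
  expect_equal(inside$direction, "none")
  low <- call_transgressive(c(0.90, 0.91, 0.89, 0.96),
                            c(1.00, 0.01), c(0.95, 0.01))
  expect_equal(low$direction, "low")
  expect_message(short <- call_transgressive(c(1.1, 1.1), c(1, 0), c(1, 0)),
                 "no call")
  expect_equal(short$direction, "none")
})

test_that("transgressivity direction flips under fitness inversion", {
  set.seed(9)
  fit <- dplyr::bind_rows(
    tibble::tibble(mutant_id = rep(sprintf("m%02d", 1:30), each = 4),
                   condition = "N", period_h = 0, replicate = rep(1:4, 30),
                   w = rep(rnorm(30, 1, 0.01), each = 4) + rnorm(120, 0, 0.004)),
    tibble::tibble(mutant_id = rep(sprintf("m%02d", 1:30), each = 4),
                   condition = "S", period_h = 0, replicate = rep(1:4, 30),
                   w = rep(rnorm(30, 0.98, 0.01), each = 4) + rnorm(120, 0, 0.004)),
    tibble::tibble(mutant_id = rep(sprintf("m%02d", 1:30), each = 4),
                   condition = "NS6", period_h = 6, replicate = rep(1:4, 30),
                   w = rep(c(rnorm(5, 1.08, 0.005), rnorm(25, 0.99, 0.004)),
                           each = 4)))
  up <- transgressive_calls(fit, "NS6")
  inv <- fit
  inv$w <- 1 / fit$w
  down <- transgressive_calls(inv, "NS6")
  high_up <- up$mutant_id[up$direction == "high"]
  expect_gt(length(high_up), 0)
  expect_true(all(down$direction[down$mutant_id %in% high_up] == "low"))
})

test_that("the transgressivity permutation null is consistent", {
  set.seed(10)
  n <- 200
  fit <- dplyr::bind_rows(
    tibble::tibble(mutant_id = rep(sprintf("m%03d", 1:n), each = 4),
                   condition = "N", period_h = 0, replicate = rep(1:4, n),
                   w = rnorm(4 * n, 1, 0.02)),
    tibble::tibble(mutant_id = rep(sprintf("m%03d", 1:n), each = 4),
                   condition = "S", period_h = 0, replicate = rep(1:4, n),
                   w = rnorm(4 * n, 1, 0.02)),
    tibble::tibble(mutant_id = rep(sprintf("m%03d", 1:n), each = 4),
                   condition = "NS6", period_h = 6, replicate = rep(1:4, n),
                   w = rnorm(4 * n, 1, 0.02)))
  calls <- transgressive_calls(fit, "NS6")
  null <- permutation_null_transgressivity(calls, n_perm = 200, seed = 11)
  spread <- max(2 * stats::sd(null$counts), 2)
  expect_lte(abs(null$expected - null$observed), spread)
  # zero-variance data can never be transgressive
  flat <- fit
  flat$w <- 1
  fcalls <- transgressive_calls(flat, "NS6")
  fnull <- permutation_null_transgressivity(fcalls, n_perm = 20, seed = 12)
  expect_equal(fnull$expected, 0)
  expect_error(permutation_null_transgressivity(fcalls, n_perm = 0), "n_perm")
})
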