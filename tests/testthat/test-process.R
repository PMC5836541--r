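make_sheet <- function(counts) {
  ids <- setdiff(names(counts), "mutant_id")
  tibble::tibble(sample_id = ids,
                 condition = sub("_.*", "", ids),
                 period_h = 0,
                 day = as.integer(sub(".*_d(\\d+)_.*", "\\1", ids)),
                 replicate = as.integer(sub(".*_r", "", ids)))
}

test_that("samples failing both depth and correlation criteria are dropped", {
  set.seed(1)
  base <- rpois(200, 500)
  counts <- tibble::tibble(
    mutant_id = sprintf("m%03d", 1:200),
    N_d1_r1 = base + rpois(200, 20),
    N_d1_r2 = base + rpois(200, 20),
    N_d1_r3 = base + rpois(200, 20),
    N_d1_r4 = sample(rpois(200, 2))   # shallow AND uncorrelated
  )
  res <- filter_samples(counts, make_sheet(counts), min_total = 3e5)
  expect_equal(res$discarded$sample_id, "N_d1_r4")
  expect_equal(ncol(res$counts), 4)
  # idempotence
  res2 <- filter_samples(res$counts, res$samples, min_total = 3e5)
  expect_equal(res2$counts, res$counts)
})

test_that("deep samples are retained regardless of correlation", {
  set.seed(2)
  counts <- tibble::tibble(
    mutant_id = sprintf("m%03d", 1:100),
    N_d1_r1 = rpois(100, 5000),
    N_d1_r2 = rpois(100, 5000),
    N_d1_r3 = sample(rpois(100, 5000))  # deep but shuffled
  )
  res <- filter_samples(counts, make_sheet(counts), min_total = 1e5)
  expect_equal(nrow(res$discarded), 0)
})

test_that("mutant filter applies a >= threshold and is idempotent", {
  counts <- tibble::tibble(mutant_id = c("a", "b", "c", "z"),
                           s1 = c(1000L, 1999L, 0L, 0L),
                           s2 = c(1000L, 0L, 2000L, 0L))
  out <- filter_mutants(counts, min_total_counts = 2000)
  expect_equal(out$mutant_id, c("a", "c"))   # 1999 dropped, 2000 kept
  expect_equal(attr(out, "discarded"), c("b", "z"))
  expect_equal(filter_mutants(out, 2000)$mutant_id, out$mutant_id)
  # independent recount oracle
  expect_equal(sum(rowSums(counts[-1]) >= 2000), nrow(out))
  expect_error(filter_mutants(counts, 1e9), "all mutants")
})

test_that("day-0 imputation takes the per-mutant donor median", {
  counts <- tibble::tibble(mutant_id = c("a", "b"),
                           t1 = c(0L, 0L),
                           d1 = c(1L, 10L), d2 = c(2L, 30L), d3 = c(9L, 20L),
                           other = c(7L, 7L))
  out <- impute_missing_day0(counts, "t1", c("d1", "d2", "d3"))
  expect_equal(out$t1, c(2, 20))
  expect_equal(out$other, counts$other)       # untouched
  same <- impute_missing_day0(counts, "t1", c("d1", "d1", "d1"))
  expect_equal(same$t1, counts$d1)
  expect_error(impute_missing_day0(counts, "t1", character(0)), "donor")
})

test_that("normalization removes pure scaling between samples", {
  set.seed(3)
  x <- rpois(300, 800)
  counts <- tibble::tibble(mutant_id = sprintf("m%03d", 1:300),
                           s1 = x, s2 = 3L * x)
  norm <- normalize_counts(counts)
  expect_equal(norm$scaled$s1, norm$scaled$s2)
  expect_equal(norm$norm$s1, norm$norm$s2, tolerance = 1e-8)
  expect_equal(unname(norm$size_factors[2] / norm$size_factors[1]), 3)
})

test_that("doubling a high count raises its normalized value by ~1 log2", {
  set.seed(4)
  counts <- tibble::tibble(mutant_id = sprintf("m%03d", 1:500),
                           s1 = rpois(500, 200), s2 = rpois(500, 200))
  counts$s1[1] <- 20000L
  doubled <- counts
  doubled$s1[1] <- 40000L
  n1 <- normalize_counts(counts)
  n2 <- normalize_counts(doubled)
  expect_equal(n2$norm$s1[1] - n1$norm$s1[1], 1, tolerance = 0.05)
})

test_that("normalization is strictly monotone within each sample", {
  set.seed(5)
  counts <- tibble::tibble(mutant_id = sprintf("m%03d", 1:200),
                           s1 = as.integer(sort(sample(0:5000, 200))),
                           s2 = rpois(200, 300))
  norm <- normalize_counts(counts)
  v <- norm$norm$s1[order(counts$s1)]
  expect_true(all(diff(v) >= 0))   # VST: monotone (flat at the low boundary)
  sorted <- sort(counts$s1)
  strict_high <- diff(sorted) > 0 & sorted[-1] > 100
  expect_true(all(diff(v)[strict_high] > 0))
  # the log2 fallback scale is strictly monotone everywhere
  nl <- normalize_counts(counts, method = "log2")
  vl <- nl$norm$s1[order(counts$s1)]
  expect_true(all(diff(vl)[diff(sorted) > 0] > 0))
  # and so are the scaled counts used downstream
  vs <- norm$scaled$s1[order(counts$s1)]
  expect_true(all(diff(vs)[diff(sorted) > 0] > 0))
})

test_that("degenerate tables are rejected", {
  counts <- tibble::tibble(mutant_id = c("a", "b"), s1 = c(1L, 2L),
                           s2 = c(0L, 0L))
  expect_error(normalize_counts(counts), "all-zero")
})
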