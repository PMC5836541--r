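glm_fixture <- function(n = 60, beta3 = 0, sd_log_w = 0.02, alpha = 0.02,
                        depth = 2e5, seed = 1) {
  truth <- sim_truth(n, sd_log_w = sd_log_w, beta3 = beta3, seed = seed)
  cfg <- sim_config(n_mutants = n, depth_per_sample = depth,
                    nb_dispersion = alpha, conditions = three_conditions(),
                    seed = seed + 1)
  sim <- simulate_experiment(cfg, truth)
  list(sim = sim, norm = normalize_counts(sim$counts, method = "log2"))
}

test_that("constant counts across samples yield near-zero coefficients", {
  samples <- tidyr::expand_grid(condition = c("N", "S", "NS6"), day = 0:3,
                                replicate = 1:4) |>
    dplyr::mutate(period_h = ifelse(condition == "NS6", 6, 0),
                  sample_id = sprintf("%s_d%d_r%d", condition, day, replicate))
  des <- glm_design(samples)
  fit <- fit_mutant_glm(rep(500, nrow(des)), des)
  expect_true(fit$converged)
  expect_equal(fit$beta1, 0, tolerance = 1e-6)
  expect_equal(fit$beta2, 0, tolerance = 1e-6)
  expect_equal(fit$beta3, 0, tolerance = 1e-6)
})

test_that("a planted per-change effect is recovered by the GLM", {
  fx <- glm_fixture(n = 150, seed = 3)
  truth <- fx$sim$truth
  planted <- utils::tail(truth$mutant_id, 15)
  truth$beta3[truth$mutant_id %in% planted] <- 0.05
  sim <- simulate_experiment(fx$sim$config, truth)
  norm <- normalize_counts(sim$counts, method = "log2")
  fits <- fit_inhomogeneity_glms(norm, sim$samples, period_h = 6,
                                 mutants = planted)
  expect_true(all(fits$converged))
  expect_lt(abs(mean(fits$beta3) - 0.05), 0.01)
  # sign property: beta3 > 0 for every strongly inhomogeneous gene
  expect_true(all(fits$beta3 > 0))
})

test_that("the fit is invariant to sample ordering", {
  fx <- glm_fixture(n = 20, seed = 5)
  ids <- fx$sim$truth$mutant_id[12:14]
  f1 <- fit_inhomogeneity_glms(fx$norm, fx$sim$samples, period_h = 6,
                               mutants = ids)
  shuffled <- fx$sim$samples[rev(seq_len(nrow(fx$sim$samples))), ]
  f2 <- fit_inhomogeneity_glms(fx$norm, shuffled, period_h = 6, mutants = ids)
  expect_equal(f1$beta3, f2$beta3, tolerance = 1e-8)
  expect_equal(f1$p_beta3, f2$p_beta3, tolerance = 1e-8)
})

test_that("noiseless exponential data are predicted to numerical precision", {
  n <- 12
  truth <- sim_truth(n, w_N = c(rep(1, 11), 1.04),
                     w_S = c(rep(1, 11), 0.97))
  cfg <- sim_config(n_mutants = n, depth_per_sample = 1e6, nb_dispersion = 0,
                    conditions = three_conditions(), seed = 2)
  sim <- simulate_experiment(cfg, truth)
  norm <- normalize_counts(sim$counts, method = "log2")
  fits <- fit_inhomogeneity_glms(norm, sim$samples, period_h = 6,
                                 mutants = truth$mutant_id[n])
  des <- attr(fits, "design")
  pred <- glm_predicted_trajectory(fits[1, ], des)
  obs <- norm$scaled[norm$scaled$mutant_id == truth$mutant_id[n], -1]
  obs_by <- tapply(as.numeric(obs[des$sample_id]),
                   paste(des$condition, des$day), mean)
  expect_equal(pred$lambda_hat,
               as.numeric(obs_by[paste(pred$condition, pred$day)]),
               tolerance = 0.02)
  # monotone in n_changes when beta3 > 0
  fit_pos <- fits[1, ]
  fit_pos$beta3 <- 0.1
  des_p <- des[des$condition == "NS6", ]
  pr <- glm_predicted_trajectory(fit_pos, des_p)
  expect_true(all(diff(pr$lambda_hat[order(pr$day)]) > 0))
})

test_that("q-values reproduce hand-computed BH thresholds", {
  p <- c(0.001, 0.002, rep(0.9, 98))
  q <- qvalues(p, method = "BH")
  # BH: q_(1) = 0.001 * 100 / 1, q_(2) = 0.002 * 100 / 2
  expect_equal(q[1], 0.1)
  expect_equal(q[2], 0.1)
  expect_equal(q[3], 0.9 * 100 / 100)
  fits <- tibble::tibble(mutant_id = sprintf("g%03d", 1:100), p_beta3 = p,
                         converged = TRUE)
  called <- call_inhomogeneous(fits, fdr = 0.2, method = "BH")
  expect_setequal(called, c("g001", "g002"))
  # all p = 1: nothing called
  fits1 <- tibble::tibble(mutant_id = c("a", "b"), p_beta3 = c(1, 1),
                          converged = TRUE)
  expect_length(call_inhomogeneous(fits1, fdr = 0.2, method = "BH"), 0)
})

test_that("the smoother pi0 estimate shrinks q-values on mixed p-values", {
  set.seed(7)
  p <- c(runif(800), rbeta(200, 0.2, 8))
  q <- suppressMessages(qvalues(p))
  pi0 <- attr(q, "pi0")
  expect_lt(pi0, 1)
  expect_gt(pi0, 0.5)
  qbh <- qvalues(p, method = "BH")
  expect_true(all(q <= qbh + 1e-12))
  # q is a monotone transform of p
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("unconverged fits are excluded from calling", {
  fits <- tibble::tibble(mutant_id = c("a", "b", "c"),
                         p_beta3 = c(1e-6, 1e-6, NA),
                         converged = c(TRUE, FALSE, TRUE))
  called <- call_inhomogeneous(fits, fdr = 0.05, method = "BH")
  expect_equal(called, "a", ignore_attr = TRUE)
  expect_error(call_inhomogeneous(fits[0, ], 0.05), "empty")
})
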