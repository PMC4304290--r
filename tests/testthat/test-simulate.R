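# Simulation generators and the experiment runner.

test_that("block covariance construction and eigenstructure", {
  cfg <- sim_config(n_blocks = 1, block_size = 2, rho = 0.6, p_total = 10)
  expect_equal(block_covariance(cfg), rbind(c(1, 0.6), c(0.6, 1)))
  cfg0 <- sim_config(n_blocks = 2, block_size = 3, rho = 0, p_total = 10)
  expect_equal(block_covariance(cfg0), diag(6))
  # exchangeable eigenvalues: 1 + (s-1) rho and 1 - rho (multiplicity s-1)
  cfg3 <- sim_config(n_blocks = 1, block_size = 5, rho = 0.3, p_total = 10)
  ev <- sort(eigen(block_covariance(cfg3), only.values = TRUE)$values)
  expect_equal(ev, sort(c(1 + 4 * 0.3, rep(0.7, 4))))
})

test_that("invalid correlations are rejected up front", {
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(n_blocks = 30, block_size = 40), "p_total")
})

test_that("normal scenario has the right shape, seeding, and moments", {
  cfg <- sim_config(n_blocks = 2, block_size = 5, rho = 0.5, p_total = 40,
                    n_train_per_class = 200, n_test_per_class = 5, seed = 31)
  sim <- generate_normal_scenario(cfg)
  expect_equal(dim(sim$train$X), c(200, 40))
  expect_equal(dim(sim$test$Y), c(5, 40))
  expect_identical(sim$informative_idx, 1:10)
  # reproducibility
  sim2 <- generate_normal_scenario(cfg)
  expect_identical(sim$train$X, sim2$train$X)
  # moments: informative means near +/- 0.6, noise near 0 (3 SE, n = 200)
  se3 <- 3 / sqrt(200)
  expect_true(all(abs(colMeans(sim$train$Y)[1:10] - 0.6) < se3))
  expect_true(all(abs(colMeans(sim$train$X)[1:10] + 0.6) < se3))
  expect_true(all(abs(colMeans(sim$train$X)[11:40]) < se3))
})

test_that("informative covariance matches the block target", {
  cfg <- sim_config(n_blocks = 1, block_size = 4, rho = 0.6, p_total = 4,
                    n_train_per_class = 20000, n_test_per_class = 5, seed = 32)
  sim <- generate_normal_scenario(cfg)
  emp <- cov(sim$train$Y[, 1:4])
  target <- block_covariance(cfg)
  # Monte-Carlo SE of a covariance entry is about sqrt(2)/sqrt(n)
  expect_lt(max(abs(emp - target)), 3 * sqrt(2) / sqrt(20000))
})

test_that("noise markers split evenly between gaussian and uniform", {
  cfg <- sim_config(n_blocks = 1, block_size = 5, rho = 0.3, p_total = 20,
                    n_train_per_class = 4000, n_test_per_class = 5, seed = 33)
  sim <- generate_normal_scenario(cfg)
  # 15 noise markers: 7 gaussian then 8 uniform
  gauss <- sim$train$X[, 6:12]; unif <- sim$train$X[, 13:20]
  expect_gt(max(abs(gauss)), 1.5)                   # gaussian tails exist
  expect_true(max(abs(unif)) <= 1)                  # uniform support
  expect_lt(abs(var(as.numeric(unif)) - 1 / 3), 0.02)
  # identical law in both classes: no mean shift anywhere in the noise
  expect_lt(max(abs(colMeans(sim$train$Y)[6:20])), 3 / sqrt(4000) * 1.2)
})

test_that("noise markers have AUC near one half", {
  cfg <- sim_config(n_blocks = 1, block_size = 5, rho = 0.3, p_total = 10,
                    n_train_per_class = 2000, n_test_per_class = 5, seed = 34)
  sim <- generate_normal_scenario(cfg)
  aucs <- vapply(6:10, function(j)
    empirical_auc(sim$train$Y[, j], sim$train$X[, j]), numeric(1))
  expect_true(all(abs(aucs - 0.5) < 0.05))
})

test_that("mixture scenario moments and degenerate weights", {
  cfg <- sim_config(p_total = 60, n_train_per_class = 20000,
                    n_test_per_class = 5, scenario = "mixture",
                    mixture_weight = 0.8, seed = 35)
  sim <- generate_mixture_scenario(cfg)
  expect_identical(sim$informative_idx, 1:50)
  # E[marker] = 0.8 * 0.6 = 0.48 for cases; the rho = 0.8 block correlation
  # keeps the 50 marker means strongly dependent, so allow 3 Monte-Carlo SEs
  # of a single (block-averaged) mean
  expect_equal(mean(colMeans(sim$train$Y)[1:50]), 0.48,
               tolerance = 3 * 1.03 / sqrt(20000) / 0.48)
  # weight 0: both classes N(0, I), AUC ~ 0.5
  cfg0 <- sim_config(p_total = 60, n_train_per_class = 4000,
                     n_test_per_class = 5, scenario = "mixture",
                     mixture_weight = 0, seed = 36)
  sim0 <- generate_mixture_scenario(cfg0)
  expect_lt(abs(empirical_auc(sim0$train$Y[, 1], sim0$train$X[, 1]) - 0.5),
            0.05)
  # weight 1 reduces to the normal scenario with a 50-block at rho 0.8
  cfg1 <- sim_config(p_total = 60, n_train_per_class = 3000,
                     n_test_per_class = 5, scenario = "mixture",
                     mixture_weight = 1, seed = 37)
  sim1 <- generate_mixture_scenario(cfg1)
  emp <- cov(sim1$train$Y[, 1:10])
  expect_lt(max(abs(emp - (diag(10) * 0.2 + 0.8))), 3 * sqrt(2) / sqrt(3000))
})

test_that("replicates are deterministic and respect support set arithmetic", {
  cfg <- sim_config(n_blocks = 1, block_size = 5, rho = 0.6, p_total = 60,
                    n_train_per_class = 15, n_test_per_class = 8)
  r1 <- run_replicate(cfg, "aucEN", rep_seed = 3, complex_support = 10,
                      n_candidates = 8)
  r2 <- run_replicate(cfg, "aucEN", rep_seed = 3, complex_support = 10,
                      n_candidates = 8)
  expect_identical(r1, r2)
  expect_lte(r1$nIMS, min(r1$nTMS, 5))
  expect_true(r1$auc >= 0 && r1$auc <= 1)
})

test_that("null configurations give chance-level AUC", {
  cfg <- sim_config(n_blocks = 1, block_size = 5, rho = 0.6, mu_abs = 0,
                    p_total = 40, n_train_per_class = 15, n_test_per_class = 10)
  aucs <- vapply(1:10, function(r)
    run_replicate(cfg, "aucEN", rep_seed = r, complex_support = 10,
                  n_candidates = 8)$auc, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("experiment summaries aggregate by the median", {
  cfg <- sim_config(n_blocks = 1, block_size = 5, rho = 0.6, p_total = 50,
                    n_train_per_class = 15, n_test_per_class = 8)
  one <- run_experiment(cfg, methods = "aucEN", n_reps = 1, base_seed = 9,
                        complex_support = 10, n_candidates = 8)
  reps <- attr(one, "replicates")
  expect_equal(one$median_auc, reps$auc[1])
  expect_equal(one$median_nIMS, reps$nIMS[1])
  three <- run_experiment(cfg, methods = "aucEN", n_reps = 3, base_seed = 9,
                          complex_support = 10, n_candidates = 8)
  r3 <- attr(three, "replicates")
  expect_equal(three$median_auc, median(r3$auc))
  expect_named(three, c("scenario", "block", "size", "rho", "method",
                        "median_auc", "median_sens95", "median_nIMS",
                        "median_nTMS", "n_reps"))
})

test_that("all four methods run end to end on a small configuration", {
  cfg <- sim_config(n_blocks = 1, block_size = 5, rho = 0.6, p_total = 40,
                    n_train_per_class = 15, n_test_per_class = 8)
  for (m in c("aucEN", "aucL", "logEN", "logL")) {
    r <- run_replicate(cfg, m, rep_seed = 5, complex_support = 10,
                       n_candidates = 8)
    expect_true(r$auc >= 0 && r$auc <= 1)
    expect_lte(r$nIMS, r$nTMS)
  }
})
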