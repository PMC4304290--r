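# The penalized covariance-regression fit, checked against independent
# oracles: the dense linear solve, closed-form soft-thresholding, brute-force
# 2-D grid minimization, and glmnet on the mapped parameterization.

test_that("objective matches direct arithmetic on the hand example", {
  s <- compute_summary_stats(hand_two_class())
  # beta = 0: sum of squared mean differences
  expect_equal(enet_objective(c(0, 0), s, lambda = 1, alpha = 0.5), 1 + 9)
  # beta = (1, 0), lambda = 1, alpha = 0.5:
  # residual (1-4, 3-4) = (-3,-1); RSS = 10; penalty 1*(0.5*1 + 0.25*1)
  expect_equal(enet_objective(c(1, 0), s, lambda = 1, alpha = 0.5),
               10 + 0.5 + 0.25)
})

test_that("objective is zero at the exact solution with no penalty", {
  d <- toy_two_class(p = 4, n_per = 20)
  s <- compute_summary_stats(d)
  beta <- solve(s$sigma_sum, s$mu_diff)
  expect_lt(enet_objective(beta, s, lambda = 0, alpha = 0.5), 1e-20)
})

test_that("unpenalized limit reproduces the closed-form oracle", {
  set.seed(42)
  for (p in c(5, 10, 20)) {
    d <- two_class_data(matrix(rnorm(30 * p), 30),
                        matrix(rnorm(30 * p, 0.3), 30))
    s <- compute_summary_stats(d)
    fit <- fit_aucpr(s, lambda = 1e-8, alpha = 0.5)
    orc <- solve_oracle(s)
    rel <- sqrt(sum((fit$beta - orc$beta)^2) / sum(orc$beta^2))
    expect_lt(rel, 1e-4)
  }
})

test_that("oracle solver handles identity and scaled systems", {
  s <- compute_summary_stats(toy_two_class(p = 3, n_per = 10))
  mu <- s$mu_diff
  s$sigma_sum <- diag(3)
  expect_equal(unname(solve_oracle(s)$beta), unname(mu))
  s$sigma_sum <- 2 * diag(3)
  expect_equal(unname(solve_oracle(s)$beta), unname(mu) / 2)
  s$sigma_sum <- matrix(1, 3, 3)  # singular
  expect_error(solve_oracle(s), "singular")
})

test_that("beta is exactly zero at lambda_max and nonzero just below", {
  set.seed(9)
  for (i in 1:20) {
    d <- two_class_data(matrix(rnorm(8 * 6), 8), matrix(rnorm(8 * 6, 0.5), 8))
    s <- compute_summary_stats(d)
    alpha <- sample(c(0.25, 0.5, 1), 1)
    lm <- lambda_max(s, alpha)
    expect_identical(unname(fit_aucpr(s, lm, alpha)$beta), rep(0, 6))
    expect_gt(length(fit_aucpr(s, 0.99 * lm, alpha)$support), 0)
  }
})

test_that("identity-design lasso reproduces the soft-threshold solution", {
  s <- compute_summary_stats(hand_two_class())
  s$sigma_sum <- diag(2)
  s$mu_diff <- c(1, 0)
  fit <- fit_aucpr(s, lambda = 1, alpha = 1)
  # min (1-b1)^2 + b2^2 + |b1| + |b2|  =>  b1 = soft(1, 1/2) = 0.5, b2 = 0
  expect_equal(unname(fit$beta), c(0.5, 0))
})

test_that("p=2 fit agrees with a brute-force grid minimizer", {
  set.seed(3)
  d <- two_class_data(matrix(rnorm(20), 10), matrix(rnorm(20, 0.5), 10))
  s <- compute_summary_stats(d)
  lam <- lambda_max(s, 0.5) / 4
  fit <- fit_aucpr(s, lam, 0.5)
  grid <- seq(-2, 2, by = 0.001)
  best <- c(NA, NA); best_val <- Inf
  for (b1 in grid) {
    obj <- (s$mu_diff[1] - s$sigma_sum[1, 1] * b1 - s$sigma_sum[1, 2] * grid)^2 +
      (s$mu_diff[2] - s$sigma_sum[2, 1] * b1 - s$sigma_sum[2, 2] * grid)^2 +
      lam * (0.5 * (abs(b1) + abs(grid)) + 0.25 * (b1^2 + grid^2))
    i <- which.min(obj)
    if (obj[i] < best_val) { best_val <- obj[i]; best <- c(b1, grid[i]) }
  }
  expect_equal(unname(fit$beta), best, tolerance = 2e-3)
})

test_that("solutions match glmnet under its parameter mapping", {
  # glmnet internally rescales the response to unit RMS, which rescales the
  # ridge half of its penalty; map (lambda, alpha) accordingly.
  set.seed(11)
  d <- toy_two_class(p = 10, n_per = 30)
  s <- compute_summary_stats(d)
  p <- s$p
  # lasso: exact mapping lambda_glmnet = lambda / (2p)
  lam <- lambda_max(s, 1) / 10
  ours <- fit_aucpr(s, lam, alpha = 1)$beta
  lam_g <- lam / (2 * p)
  lseq <- exp(seq(log(lam_g * 50), log(lam_g), length.out = 60))
  g <- glmnet::glmnet(s$sigma_sum, s$mu_diff, alpha = 1, lambda = lseq,
                      standardize = FALSE, intercept = FALSE,
                      thresh = 1e-14, maxit = 1e7)
  expect_equal(unname(ours), as.numeric(g$beta[, 60]), tolerance = 1e-6)
  # elastic net: ridge part rescaled by rms(y)
  lam <- lambda_max(s, 0.5) / 10
  ours <- fit_aucpr(s, lam, alpha = 0.5)$beta
  rms_y <- sqrt(mean(s$mu_diff^2))
  l1 <- lam * 0.5 / (2 * p); l2 <- lam * 0.5 * rms_y / (2 * p)
  lseq <- exp(seq(log((l1 + l2) * 50), log(l1 + l2), length.out = 60))
  g <- glmnet::glmnet(s$sigma_sum, s$mu_diff, alpha = l1 / (l1 + l2),
                      lambda = lseq, standardize = FALSE, intercept = FALSE,
                      thresh = 1e-14, maxit = 1e7)
  expect_equal(unname(ours), as.numeric(g$beta[, 60]), tolerance = 1e-6)
})

test_that("fitting never increases the objective above the zero vector", {
  set.seed(5)
  for (i in 1:10) {
    p <- sample(3:12, 1)
    d <- two_class_data(matrix(rnorm(15 * p), 15),
                        matrix(rnorm(15 * p, 0.4), 15))
    s <- compute_summary_stats(d)
    alpha <- runif(1, 0.1, 1)
    lam <- runif(1) * lambda_max(s, alpha)
    fit <- fit_aucpr(s, lam, alpha)
    expect_lte(enet_objective(fit, s, lam, alpha),
               enet_objective(rep(0, p), s, lam, alpha) + 1e-12)
  }
})

test_that("degenerate zero mean difference warns and returns zero", {
  X <- matrix(rnorm(40), 10)
  s <- compute_summary_stats(two_class_data(X, X))
  expect_warning(fit <- fit_aucpr(s, 1, 0.5), "identically zero")
  expect_identical(unname(fit$beta), rep(0, 4))
})

test_that("non-convergence raises a condition carrying the last iterate", {
  d <- toy_two_class(p = 20, n_per = 25, shift = 0.5)
  s <- compute_summary_stats(d)
  err <- tryCatch(fit_aucpr(s, lambda_max(s, 0.5) / 100, 0.5, max_sweeps = 2),
                  aucpr_numerical_error = function(e) e)
  expect_s3_class(err, "aucpr_numerical_error")
  expect_length(err$beta_last, 20)
  expect_gt(err$gap, 0)
})

test_that("standardized fits solve the rescaled problem, not the default one", {
  d <- toy_two_class(p = 8, n_per = 20)
  s <- compute_summary_stats(d)
  lam <- lambda_max(s, 0.5) / 5
  plain <- fit_aucpr(s, lam, 0.5)
  std <- fit_aucpr(s, lam, 0.5, standardize = TRUE)
  expect_false(isTRUE(all.equal(plain$beta, std$beta)))
  # at lambda ~ 0 both recover the oracle
  expect_equal(fit_aucpr(s, 1e-9, 0.5, standardize = TRUE)$beta,
               solve_oracle(s)$beta, tolerance = 1e-4)
})

test_that("scores are linear projections with rank invariance", {
  d <- toy_two_class(p = 4, n_per = 10)
  beta <- c(0, 1, 0, 0)
  expect_equal(score_samples(beta, d$X), unname(d$X[, 2]))
  expect_equal(score_samples(rep(0, 4), d$X), rep(0, 10))
  s1 <- score_samples(c(1, -2, 0.5, 3), d$X)
  s2 <- score_samples(2.5 * c(1, -2, 0.5, 3), d$X)
  expect_equal(order(s1), order(s2))
  expect_error(score_samples(c(1, 2), d$X), "columns")
})

test_that("oracle combination approaches the binormal optimal AUC", {
  # X ~ N(-0.6, A(0.3)), Y ~ N(+0.6, A(0.3)), p = 6: the best linear score
  # has AUC Phi(sqrt(mu' Sigma_sum^-1 mu)) at the true parameters.
  cfg <- sim_config(n_blocks = 1, block_size = 6, rho = 0.3, p_total = 6,
                    n_train_per_class = 2000, n_test_per_class = 4000,
                    seed = 77)
  sim <- generate_normal_scenario(cfg)
  beta <- solve_oracle(compute_summary_stats(sim$train))
  auc <- empirical_auc(score_samples(beta, sim$test$Y),
                       score_samples(beta, sim$test$X))
  mu <- rep(1.2, 6)
  sigma_sum <- 2 * block_covariance(cfg)
  theo <- pnorm(sqrt(drop(mu %*% solve(sigma_sum, mu))))
  expect_equal(auc, theo, tolerance = 0.02)
})
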