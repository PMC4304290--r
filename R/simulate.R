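# Simulation generators for benchmarking: informative markers from
# multivariate normal classes with block-exchangeable correlation and mean
# vectors +/- mu_abs, non-informative markers split evenly between N(0,1)
# and Uniform[-1,1], padded to p_total markers; plus a contaminated-normal
# mixture scenario.  Defaults reproduce the study design: 40 + 40 training
# and 20 + 20 test samples, 1000 markers, per-marker design AUC
# Phi(2 * 0.6 / sqrt(2)) = 0.8.

#' Simulation configuration
#'
#' @param n_blocks number of independent informative blocks.
#' @param block_size markers per block.
#' @param rho within-block exchangeable correlation; between-block
#'   correlation is 0.  Must satisfy `-1/(block_size - 1) < rho < 1`.
#' @param mu_abs absolute per-marker class mean (cases at `+mu_abs`, controls
#'   at `-mu_abs`); the default 0.6 gives each informative marker a design
#'   AUC of \eqn{\Phi(1.2/\sqrt 2) = 0.8}.
#' @param p_total total marker count after padding with noise markers.
#' @param n_train_per_class,n_test_per_class samples per class.
#' @param scenario `"normal"` or `"mixture"` (contaminated normal).
#' @param mixture_weight probability of the signal component in the mixture
#'   scenario.
#' @param seed integer seed.
#' @param randomize_positions if `TRUE`, marker positions are permuted (the
#'   informative indices are recorded either way); by default informative
#'   markers come first, then Gaussian noise, then uniform noise.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_blocks = 1L, block_size = 40L, rho = 0.6,
                       mu_abs = 0.6, p_total = 1000L,
                       n_train_per_class = 40L, n_test_per_class = 20L,
                       scenario = c("normal", "mixture"),
                       mixture_weight = 0.8, seed = NULL,
                       randomize_positions = FALSE) {
  scenario <- match.arg(scenario)
  n_blocks <- as.integer(n_blocks); block_size <- as.integer(block_size)
  p_total <- as.integer(p_total)
  if (n_blocks < 1L || block_size < 1L)
    stop_validation("n_blocks and block_size must be positive")
  if (rho >= 1 || (block_size > 1L && rho <= -1 / (block_size - 1)))
    stop_validation("rho must satisfy -1/(block_size-1) < rho < 1 (positive-definite block)")
  if (n_blocks * block_size > p_total)
    stop_validation("n_blocks * block_size must not exceed p_total")
  if (mixture_weight < 0 || mixture_weight > 1)
    stop_validation("mixture_weight must be in [0, 1]")
  structure(list(n_blocks = n_blocks, block_size = block_size, rho = rho,
                 mu_abs = mu_abs, p_total = p_total,
                 n_train_per_class = as.integer(n_train_per_class),
                 n_test_per_class = as.integer(n_test_per_class),
                 scenario = scenario, mixture_weight = mixture_weight,
                 seed = seed, randomize_positions = randomize_positions),
            class = "sim_config")
}

#' Block-diagonal exchangeable covariance of the informative markers
#'
#' `n_blocks` copies of the exchangeable matrix A(rho) (unit diagonal, rho
#' off-diagonal) on the diagonal, zero elsewhere.  A(rho) has eigenvalues
#' `1 + (size-1) rho` and `1 - rho` (multiplicity size-1).
#'
#' @param cfg a [sim_config()].
#' @return A `(n_blocks * block_size)` square covariance matrix.
#' @export
block_covariance <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  s <- cfg$block_size
  A <- matrix(cfg$rho, s, s)
  diag(A) <- 1
  if (1 + (s - 1) * cfg$rho <= 0 || (s > 1L && 1 - cfg$rho <= 0))
    stop_validation("A(rho) is not positive definite")
  kronecker(diag(cfg$n_blocks), A)
}

# Multivariate normal draws: n x p matrix with mean vector mu and upper
# Cholesky factor R of the covariance (cov = R'R).
rmvn_chol <- function(n, mu, R) {
  z <- matrix(stats::rnorm(n * ncol(R)), n, ncol(R))
  sweep(z %*% R, 2L, mu, "+")
}

# Noise markers: floor(n_noise/2) standard normal columns, the remainder
# Uniform[-1,1]; the identical generation law is used for both classes.
noise_block <- function(n_samples, n_noise) {
  n_gauss <- n_noise %/% 2L
  n_unif <- n_noise - n_gauss
  cbind(matrix(stats::rnorm(n_samples * n_gauss), n_samples, n_gauss),
        matrix(stats::runif(n_samples * n_unif, -1, 1), n_samples, n_unif))
}

assemble_scenario <- function(cfg, draw_class) {
  p_inf <- cfg$n_blocks * cfg$block_size
  n_noise <- cfg$p_total - p_inf
  one_set <- function(n_samples, mu_sign) {
    cbind(draw_class(n_samples, mu_sign), noise_block(n_samples, n_noise))
  }
  ntr <- cfg$n_train_per_class; nte <- cfg$n_test_per_class
  train_x <- one_set(ntr, -1); train_y <- one_set(ntr, +1)
  test_x <- one_set(nte, -1); test_y <- one_set(nte, +1)
  informative_idx <- seq_len(p_inf)
  marker_ids <- sprintf("m%04d", seq_len(cfg$p_total))
  if (cfg$randomize_positions) {
    perm <- sample(cfg$p_total)
    train_x <- train_x[, perm]; train_y <- train_y[, perm]
    test_x <- test_x[, perm]; test_y <- test_y[, perm]
    informative_idx <- match(seq_len(p_inf), perm)
  }
  structure(list(
    train = two_class_data(train_x, train_y, marker_ids),
    test = make_two_class(test_x, test_y, marker_ids, min_per_class = 1L),
    informative_idx = sort(informative_idx),
    config = cfg), class = "aucpr_sim")
}

#' @export
print.aucpr_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated %s-scenario data: %d informative / %d total markers, %d+%d train, %d+%d test\n",
              cfg$scenario, length(x$informative_idx), cfg$p_total,
              cfg$n_train_per_class, cfg$n_train_per_class,
              cfg$n_test_per_class, cfg$n_test_per_class))
  invisible(x)
}

#' Generate data under the multivariate normal scenario
#'
#' Informative markers are drawn from \eqn{N(\pm\mu, \Sigma)} with
#' \eqn{\Sigma} the block-exchangeable covariance of [block_covariance()];
#' cases have mean `+mu_abs` and controls `-mu_abs` on every informative
#' marker.  Noise markers (identically distributed in both classes) pad the
#' table to `p_total`.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `aucpr_sim` with `train` and `test`
#'   ([two_class_data()] objects), `informative_idx`, and `config`.
#' @export
generate_normal_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  R <- chol(block_covariance(cfg))
  p_inf <- cfg$n_blocks * cfg$block_size
  with_seed(cfg$seed, assemble_scenario(cfg, function(n, mu_sign)
    rmvn_chol(n, rep(mu_sign * cfg$mu_abs, p_inf), R)))
}

#' Generate data under the contaminated-normal mixture scenario
#'
#' Each sample's informative markers are drawn from the signal component
#' \eqn{N(\pm\mu, \Sigma(0.8))} with probability `mixture_weight` and from
#' \eqn{N(0, I)} otherwise.  The informative panel is a single exchangeable
#' block of 50 markers with correlation 0.8 (the configured `n_blocks`,
#' `block_size` and `rho` are overridden accordingly); noise markers are
#' generated as in the normal scenario.
#'
#' @param cfg a [sim_config()] (its `mixture_weight`, sample sizes, `mu_abs`
#'   and `p_total` are honored).
#' @return As [generate_normal_scenario()].
#' @export
generate_mixture_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$n_blocks <- 1L; cfg$block_size <- 50L; cfg$rho <- 0.8
  cfg$scenario <- "mixture"
  if (cfg$p_total < 50L) stop_validation("p_total must be at least 50")
  R <- chol(block_covariance(cfg))
  p_inf <- 50L
  draw <- function(n, mu_sign) {
    signal <- stats::rbinom(n, 1L, cfg$mixture_weight) == 1L
    out <- matrix(stats::rnorm(n * p_inf), n, p_inf)   # N(0, I) component
    if (any(signal)) {
      out[signal, ] <- rmvn_chol(sum(signal),
                                 rep(mu_sign * cfg$mu_abs, p_inf), R)
    }
    out
  }
  with_seed(cfg$seed, assemble_scenario(cfg, draw))
}

generate_scenario <- function(cfg) {
  if (cfg$scenario == "mixture") generate_mixture_scenario(cfg)
  else generate_normal_scenario(cfg)
}

#' Run one simulation replicate of a method
#'
#' Generates a fresh training and test set from `cfg` at `rep_seed`, fits the
#' requested method on the training data (penalty strength tuned by 3-fold
#' empirical-AUC cross-validation), scores the test samples, and reports the
#' test AUC, sensitivity at specificity 0.95, the number of true informative
#' markers selected (nIMS) and the total markers selected (nTMS).
#'
#' @param cfg a [sim_config()].
#' @param method `"aucEN"`, `"aucL"` (covariance regression, elastic net /
#'   lasso), `"logEN"` or `"logL"` (penalized logistic baseline).
#' @param rep_seed integer seed for this replicate.
#' @param complex_support,n_candidates grid settings, see
#'   [make_lambda_grid()].
#' @param K cross-validation folds.
#' @return A one-row data frame with columns `method`, `auc`, `sens95`,
#'   `nIMS`, `nTMS`, `lambda`, `rep_seed`.
#' @export
run_replicate <- function(cfg, method = c("aucEN", "aucL", "logEN", "logL"),
                          rep_seed, complex_support = 100L,
                          n_candidates = 50L, K = 3L) {
  stopifnot(inherits(cfg, "sim_config"))
  method <- match.arg(method)
  cfg$seed <- as.integer(rep_seed)
  dat <- generate_scenario(cfg)
  alpha <- if (method %in% c("aucEN", "logEN")) 0.5 else 1
  cv_seed <- derive_seed(rep_seed, 104729)
  if (method %in% c("aucEN", "aucL")) {
    fit <- fit_aucpr_cv(dat$train, K = K, alpha = alpha,
                        complex_support = complex_support,
                        n_candidates = n_candidates, seed = cv_seed)
    beta <- fit$coef
  } else {
    grid <- logistic_lambda_grid(dat$train, alpha = alpha,
                                 n_candidates = n_candidates)
    cv <- cv_select(dat$train, grid, K = K, alpha = alpha, seed = cv_seed,
                    fitter = "logistic")
    beta <- fit_penalized_logistic(dat$train, cv$selected_lambda, alpha)
  }
  sy <- score_samples(beta, dat$test$Y)
  sx <- score_samples(beta, dat$test$X)
  data.frame(method = method,
             auc = empirical_auc(sy, sx, ties = "strict"),
             sens95 = sensitivity_at_specificity(sy, sx, 0.95),
             nIMS = length(intersect(beta$support, dat$informative_idx)),
             nTMS = length(beta$support),
             lambda = beta$lambda,
             rep_seed = as.integer(rep_seed))
}

#' Run a replicated simulation experiment
#'
#' Repeats [run_replicate()] `n_reps` times per method with replicate seeds
#' derived deterministically from `base_seed`, and summarizes each method by
#' the across-replicate medians of AUC, sensitivity at specificity 0.95,
#' nIMS and nTMS.
#'
#' @inheritParams run_replicate
#' @param methods character vector of methods to run.
#' @param n_reps number of replicates per method.
#' @param base_seed integer seed from which replicate seeds are derived.
#' @param ... passed to [run_replicate()].
#' @return A data frame of class `aucpr_experiment` with one row per method:
#'   `scenario`, `block`, `size`, `rho`, `method`, `median_auc`,
#'   `median_sens95`, `median_nIMS`, `median_nTMS`, `n_reps`.  The
#'   per-replicate long table is attached as attribute `"replicates"`.
#' @export
run_experiment <- function(cfg, methods = "aucEN", n_reps = 100L,
                           base_seed = 1L, ...) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_reps < 1L) stop_validation("n_reps must be at least 1")
  reps <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    rep_seed <- derive_seed(base_seed, r)
    do.call(rbind, lapply(methods, function(mth)
      run_replicate(cfg, mth, rep_seed, ...)))
  }))
  summ <- do.call(rbind, lapply(methods, function(mth) {
    sub <- reps[reps$method == mth, ]
    data.frame(scenario = cfg$scenario, block = cfg$n_blocks,
               size = cfg$block_size, rho = cfg$rho, method = mth,
               median_auc = stats::median(sub$auc),
               median_sens95 = stats::median(sub$sens95),
               median_nIMS = stats::median(sub$nIMS),
               median_nTMS = stats::median(sub$nTMS),
               n_reps = as.integer(n_reps))
  }))
  class(summ) <- c("aucpr_experiment", "data.frame")
  attr(summ, "replicates") <- reps
  summ
}
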