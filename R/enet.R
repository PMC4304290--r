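# Core penalized fit: the AUC-optimal combination recast as an elastic-net
# regression of mu_diff (p "observations") on sigma_sum (p "predictors"),
# with no intercept and, by default, no column standardization.  The solver
# is the package's own coordinate descent (src/cd_enet.cpp) on the unscaled
# objective
#   ||mu - Sigma b||^2 + lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2),
# so beta = 0 exactly when lambda >= 2 ||Sigma' mu||_inf / alpha.

new_aucpr_coef <- function(beta, marker_ids, lambda, alpha, n_iter = NA_integer_,
                           intercept = NULL) {
  beta <- as.numeric(beta)
  names(beta) <- marker_ids
  structure(list(beta = beta,
                 support = which(abs(beta) > AUCPR_ZERO_TOL),
                 marker_ids = marker_ids,
                 lambda = lambda, alpha = alpha,
                 n_iter = n_iter, intercept = intercept),
            class = "aucpr_coef")
}

#' @export
print.aucpr_coef <- function(x, ...) {
  cat(sprintf("Marker combination: %d of %d coefficients nonzero (lambda = %.4g, alpha = %.2f)\n",
              length(x$support), length(x$beta), x$lambda, x$alpha))
  invisible(x)
}

#' Elastic-net objective of the mean-difference regression
#'
#' Evaluates \eqn{\|\hat\mu - \hat\Sigma\beta\|_2^2 + \lambda(\alpha
#' \|\beta\|_1 + \frac{1-\alpha}{2}\|\beta\|_2^2)} with the residual term
#' summed over the p coordinates of \eqn{\hat\mu} (no sample-size rescaling).
#'
#' @param beta numeric vector of length p, or an `aucpr_coef` object.
#' @param stats an `aucpr_stats` object from [compute_summary_stats()].
#' @param lambda penalty strength, >= 0.
#' @param alpha elastic-net mixing parameter in \[0, 1\] (1 = lasso).
#' @return The scalar objective value.
#' @export
enet_objective <- function(beta, stats, lambda, alpha = 0.5) {
  if (inherits(beta, "aucpr_coef")) beta <- beta$beta
  beta <- as.numeric(beta)
  if (length(beta) != stats$p)
    stop_validation("beta length does not match the number of markers")
  resid <- stats$mu_diff - drop(stats$sigma_sum %*% beta)
  sum(resid^2) + lambda * (alpha * sum(abs(beta)) +
                             (1 - alpha) / 2 * sum(beta^2))
}

#' Penalty strength at which the fitted combination is exactly zero
#'
#' @inheritParams enet_objective
#' @return \eqn{\lambda_{max} = 2\|\hat\Sigma'\hat\mu\|_\infty / \alpha}.
#' @export
lambda_max <- function(stats, alpha = 0.5) {
  if (alpha <= 0)
    stop_validation("lambda_max requires alpha > 0 (some L1 penalty)")
  2 * max(abs(crossprod(stats$sigma_sum, stats$mu_diff))) / alpha
}

#' Fit the penalized AUC-optimal marker combination at fixed lambda
#'
#' Minimizes the elastic-net objective of [enet_objective()] by coordinate
#' descent.  There is no intercept (the underlying moment equation
#' \eqn{\hat\mu = \hat\Sigma\beta} has none) and the covariance "design"
#' columns are not standardized by default; `standardize = TRUE` rescales each
#' column to unit root-mean-square before fitting (and back-transforms the
#' coefficients) as a sensitivity option.
#'
#' @inheritParams enet_objective
#' @param stats an `aucpr_stats` object.
#' @param lambda penalty strength, >= 0.  At `lambda = 0` the pooled
#'   covariance must be nonsingular.
#' @param standardize logical; rescale design columns to unit RMS first.
#' @param tol convergence tolerance on the maximum coordinate update.
#' @param max_sweeps maximum number of coordinate sweeps.
#' @param beta_init optional warm-start coefficient vector.
#' @return An object of class `aucpr_coef`: list with `beta` (named numeric),
#'   `support` (indices with |beta| > 1e-10), `marker_ids`, `lambda`,
#'   `alpha`, `n_iter`.
#' @examples
#' d <- two_class_data(matrix(rnorm(40), 10), matrix(rnorm(40, 1), 10))
#' s <- compute_summary_stats(d)
#' fit_aucpr(s, lambda = lambda_max(s, 0.5) / 4)
#' @export
fit_aucpr <- function(stats, lambda, alpha = 0.5, standardize = FALSE,
                      tol = 1e-7, max_sweeps = 1e5, beta_init = NULL) {
  path <- enet_path(stats, lambda, alpha, standardize, tol, max_sweeps,
                    beta_init)
  new_aucpr_coef(path$beta[, 1L], stats$marker_ids, lambda, alpha,
                 n_iter = path$iters[1L])
}

# Precomputed quadratic form of the penalized least-squares problem.  The
# Gram matrix G = X'X and q = X'y are built once per design (one BLAS
# crossprod) and reused by every fit along a path, across CV folds and
# through the support-size bisection.
enet_problem <- function(stats, standardize = FALSE) {
  stopifnot(inherits(stats, "aucpr_stats"))
  X <- stats$sigma_sum
  p <- stats$p
  scale_fac <- rep(1, p)
  if (standardize) {
    scale_fac <- sqrt(colMeans(X^2))
    scale_fac[scale_fac == 0] <- 1
    X <- sweep(X, 2L, scale_fac, "/")
  }
  list(G = crossprod(X), q = drop(crossprod(X, stats$mu_diff)),
       scale_fac = scale_fac, p = p, marker_ids = stats$marker_ids,
       mu_zero = all(stats$mu_diff == 0))
}

enet_path_prob <- function(prob, lambdas, alpha = 0.5, tol = 1e-7,
                           max_sweeps = 1e5, beta_init = NULL) {
  if (any(lambdas < 0)) stop_validation("lambda must be nonnegative")
  if (alpha < 0 || alpha > 1) stop_validation("alpha must be in [0, 1]")
  p <- prob$p
  if (prob$mu_zero) {
    warning("mean-difference vector is identically zero; returning beta = 0")
    return(list(beta = matrix(0, p, length(lambdas)),
                iters = integer(length(lambdas)),
                converged = rep(TRUE, length(lambdas))))
  }
  init <- if (is.null(beta_init)) numeric(p)
          else as.numeric(beta_init) * prob$scale_fac
  out <- cd_enet_path(prob$G, prob$q, as.numeric(lambdas), alpha, init,
                      tol, as.integer(max_sweeps))
  if (!all(out$converged)) {
    bad <- which(!out$converged)[1L]
    stop_numerical(
      sprintf("coordinate descent did not converge at lambda = %.6g (max update %.3g after %d sweeps)",
              lambdas[bad], out$gap[bad], out$iters[bad]),
      data = list(beta_last = out$beta[, bad] / prob$scale_fac,
                  gap = out$gap[bad]))
  }
  beta <- out$beta / prob$scale_fac
  list(beta = beta, iters = out$iters, converged = out$converged)
}

# Path version used by cross-validation and the support-size bisection:
# lambdas should be descending so warm starts flow from sparse to dense.
enet_path <- function(stats, lambdas, alpha = 0.5, standardize = FALSE,
                      tol = 1e-7, max_sweeps = 1e5, beta_init = NULL) {
  enet_path_prob(enet_problem(stats, standardize), lambdas, alpha, tol,
                 max_sweeps, beta_init)
}

#' Closed-form AUC-optimal combination for small marker panels
#'
#' Dense reference solver for the unpenalized combination
#' \eqn{\beta = \hat\Sigma^{-1}\hat\mu}; usable only when the pooled sample
#' covariance is nonsingular (p smaller than the combined sample size).
#'
#' @param stats an `aucpr_stats` object with nonsingular `sigma_sum`.
#' @return An `aucpr_coef` object with `lambda = 0`.
#' @export
solve_oracle <- function(stats) {
  stopifnot(inherits(stats, "aucpr_stats"))
  beta <- tryCatch(solve(stats$sigma_sum, stats$mu_diff),
                   error = function(e) stop_numerical(
                     paste0("pooled covariance is singular; the closed-form ",
                            "combination needs p < m + n - 1: ",
                            conditionMessage(e))))
  new_aucpr_coef(beta, stats$marker_ids, lambda = 0, alpha = NA_real_)
}

#' Linear scores of samples under a fitted combination
#'
#' @param beta an `aucpr_coef` object or a numeric coefficient vector.
#' @param samples numeric matrix (samples x markers) with p columns.
#' @return Numeric vector of scores `samples %*% beta`; higher scores are more
#'   disease-like.
#' @export
score_samples <- function(beta, samples) {
  if (inherits(beta, "aucpr_coef")) beta <- beta$beta
  samples <- as.matrix(samples)
  if (ncol(samples) != length(beta))
    stop_validation(sprintf("samples have %d columns but beta has length %d",
                            ncol(samples), length(beta)))
  drop(samples %*% as.numeric(beta))
}
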