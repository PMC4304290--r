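# Tuning-parameter machinery: support size along the regularization path,
# bisection search for the lambda giving a requested support, log-even
# candidate grids, and K-fold cross-validation scored with the summed
# empirical AUC of the held-out folds.

#' Number of nonzero coefficients at a given penalty strength
#'
#' @inheritParams fit_aucpr
#' @param ... further arguments passed to [fit_aucpr()].
#' @return Integer support size r(lambda).
#' @export
support_size <- function(stats, lambda, alpha = 0.5, ...) {
  length(fit_aucpr(stats, lambda, alpha, ...)$support)
}

#' Find the penalty strength yielding a requested support size
#'
#' Starting from \eqn{\lambda_{max}} (where the fit is empty), the penalty is
#' halved until at least `k` coefficients are nonzero, which brackets the
#' target; bisection on the bracket midpoint then shrinks it until the
#' support is exactly `k` or the relative bracket width falls below
#' `bracket_tol`.  If the path skips support `k` (support sizes can jump),
#' the bracket endpoint whose support is nearest to `k` is returned,
#' preferring the sparser side on ties, with `exact = FALSE` recorded in the
#' attributes.
#'
#' @inheritParams fit_aucpr
#' @param k requested number of nonzero coefficients, 1 <= k <= p.
#' @param max_iter maximum bisection iterations.
#' @param bracket_tol relative bracket width at which bisection stops.
#' @param ... passed to the underlying fits.
#' @return The selected lambda (scalar) with attributes `support` (achieved
#'   support size), `exact` (logical), and `bracket_supports`
#'   (c(dense side, sparse side)).
#' @export
lambda_for_support <- function(stats, k, alpha = 0.5, max_iter = 100L,
                               bracket_tol = 1e-6, ...) {
  stopifnot(inherits(stats, "aucpr_stats"))
  lambda_for_support_prob(enet_problem(stats), stats, k, alpha, max_iter,
                          bracket_tol, ...)
}

# Internal workhorse taking a precomputed enet_problem so the Gram matrix is
# shared across the whole bisection (and with the caller's other fits).
lambda_for_support_prob <- function(prob, stats, k, alpha = 0.5,
                                    max_iter = 100L, bracket_tol = 1e-6,
                                    ...) {
  k <- as.integer(k)
  if (k < 1L || k > stats$p)
    stop_validation("k must satisfy 1 <= k <= p")
  lam_hi <- lambda_max(stats, alpha)
  warm <- numeric(stats$p)
  r_of <- function(lam) {
    fit <- enet_path_prob(prob, lam, alpha, beta_init = warm, ...)
    warm <<- fit$beta[, 1L]
    sum(abs(warm) > AUCPR_ZERO_TOL)
  }
  # Halving phase: walk down from lambda_max until the fit is at least as
  # dense as requested.
  lam2 <- lam_hi; r2 <- 0L          # sparse end: r2 <= k
  lam1 <- lam_hi; r1 <- 0L
  halvings <- 0L
  while (r1 < k) {
    if (halvings > 60L)
      stop_numerical(sprintf(
        "support %d is unattainable on this path (reached r = %d at lambda = %.3g); note the covariance rank bound min(p, m + n - 2) = %d",
        k, r1, lam1, min(stats$p, stats$m + stats$n - 2L)))
    lam2 <- lam1; r2 <- r1
    lam1 <- lam1 / 2
    # a solver stall at vanishing lambda means the requested support lies
    # beyond what the path can reach before the problem turns singular
    r1 <- tryCatch(r_of(lam1), aucpr_numerical_error = function(e)
      stop_numerical(sprintf(
        "support %d is unattainable: the path saturates at r = %d (lambda = %.3g) before the unpenalized problem turns singular (rank bound %d)",
        k, r2, lam2, min(stats$p, stats$m + stats$n - 2L))))
    halvings <- halvings + 1L
  }
  if (r1 == k) {
    return(structure(lam1, support = k, exact = TRUE,
                     bracket_supports = c(r1, r2)))
  }
  # Bisection: invariant r(lam1) >= k >= r(lam2) with lam1 < lam2.
  for (iter in seq_len(max_iter)) {
    if ((lam2 - lam1) / lam2 < bracket_tol) break
    lam_m <- (lam1 + lam2) / 2
    r_m <- r_of(lam_m)
    if (r_m == k) {
      return(structure(lam_m, support = k, exact = TRUE,
                       bracket_supports = c(r1, r2)))
    } else if (r_m < k) {
      lam2 <- lam_m; r2 <- r_m
    } else {
      lam1 <- lam_m; r1 <- r_m
    }
  }
  if ((lam2 - lam1) / lam2 >= bracket_tol) {
    stop_numerical(sprintf(
      "bisection for support %d did not converge in %d iterations (bracketing supports %d and %d)",
      k, max_iter, r1, r2))
  }
  # Support k skipped by the path: nearest achievable, sparser side on ties.
  if (abs(r2 - k) <= abs(r1 - k)) {
    structure(lam2, support = r2, exact = FALSE, bracket_supports = c(r1, r2))
  } else {
    structure(lam1, support = r1, exact = FALSE, bracket_supports = c(r1, r2))
  }
}

#' Log-even candidate grid for the penalty strength
#'
#' The dense end `lambda_l` is the penalty selecting `complex_support`
#' markers (default 100, capped at `min(p, m + n - 2)`, the rank of the
#' pooled sample covariance) and the sparse end `lambda_u` selects a single
#' marker; candidates are spaced evenly in log lambda between them,
#' descending from `lambda_u`.
#'
#' @inheritParams lambda_for_support
#' @param complex_support support size of the most complex candidate model.
#' @param n_candidates number of grid points.
#' @param standardize passed to the underlying fits.
#' @param ... passed to [lambda_for_support()].
#' @return An object of class `lambda_grid`: list with `lambda_l`,
#'   `lambda_u`, `candidates` (descending), `n_candidates`, `alpha`, and the
#'   achieved endpoint supports `support_l`, `support_u`.
#' @export
make_lambda_grid <- function(stats, complex_support = 100L, n_candidates = 50L,
                             alpha = 0.5, standardize = FALSE, ...) {
  stopifnot(inherits(stats, "aucpr_stats"))
  complex_support <- min(as.integer(complex_support), stats$p,
                         stats$m + stats$n - 2L)
  if (complex_support <= 1L)
    stop_validation("complex_support must exceed 1 after capping at min(p, m + n - 2)")
  prob <- enet_problem(stats, standardize)
  lam_l <- lambda_for_support_prob(prob, stats, complex_support, alpha, ...)
  lam_u <- lambda_for_support_prob(prob, stats, 1L, alpha, ...)
  if (!(as.numeric(lam_l) < as.numeric(lam_u)))
    stop_numerical("degenerate lambda range: dense-end lambda is not below sparse-end lambda")
  candidates <- exp(seq(log(as.numeric(lam_u)), log(as.numeric(lam_l)),
                        length.out = n_candidates))
  structure(list(lambda_l = as.numeric(lam_l), lambda_u = as.numeric(lam_u),
                 candidates = candidates, n_candidates = as.integer(n_candidates),
                 alpha = alpha,
                 support_l = attr(lam_l, "support"),
                 support_u = attr(lam_u, "support")),
            class = "lambda_grid")
}

#' @export
print.lambda_grid <- function(x, ...) {
  cat(sprintf("Lambda grid: %d candidates in [%.4g, %.4g] (supports %d down to %d)\n",
              x$n_candidates, x$lambda_l, x$lambda_u, x$support_l, x$support_u))
  invisible(x)
}

# Stratified fold assignment: per-class fold sizes n %/% K (+1 for the first
# n %% K folds), assigned by seeded shuffle.
fold_assignments <- function(n_class, K) {
  sizes <- rep(n_class %/% K, K) + (seq_len(K) <= n_class %% K)
  sample(rep(seq_len(K), times = sizes))
}

#' Cross-validated selection of the penalty strength by empirical AUC
#'
#' Stratified K-fold cross-validation: both classes are partitioned into K
#' folds; for each candidate lambda and each fold, the model is refit from
#' scratch on the out-of-fold samples (recomputing the summary statistics for
#' the covariance-regression fitter) and the held-out fold's empirical AUC
#' (strict ties) is accumulated.  The CV score of a lambda is the sum of its
#' K fold AUCs; the selected lambda maximizes the score, with ties broken
#' toward the larger (sparser) lambda.
#'
#' @param d a [two_class_data()] object.
#' @param grid a [make_lambda_grid()] object (or any list with a descending
#'   `candidates` vector).
#' @param K number of folds (default 3).
#' @param alpha elastic-net mixing parameter.
#' @param seed integer seed for the fold shuffle (optional).
#' @param fitter `"aucpr"` (covariance regression) or `"logistic"`
#'   (penalized logistic regression baseline).
#' @param folds optional list with integer vectors `x` and `y` of per-sample
#'   fold indices, overriding the seeded assignment (used mainly for tests).
#' @param standardize passed to the aucpr fitter.
#' @return An object of class `cv_result`: list with `lambda` (candidates),
#'   `cv_scores`, `fold_auc` (K x n_candidates matrix), `selected_lambda`,
#'   `fold_x`, `fold_y`, `K`, `alpha`, `fitter`.
#' @export
cv_select <- function(d, grid, K = 3L, alpha = 0.5, seed = NULL,
                      fitter = c("aucpr", "logistic"), folds = NULL,
                      standardize = FALSE) {
  stopifnot(inherits(d, "two_class_data"))
  fitter <- match.arg(fitter)
  K <- as.integer(K)
  if (d$m < K || d$n < K)
    stop_validation("each class needs at least K samples for K-fold CV")
  lambdas <- grid$candidates
  if (is.unsorted(rev(lambdas)))
    stop_validation("grid candidates must be descending")
  if (is.null(folds)) {
    folds <- with_seed(seed, list(x = fold_assignments(d$m, K),
                                  y = fold_assignments(d$n, K)))
  }
  fold_auc <- matrix(NA_real_, K, length(lambdas))
  for (i in seq_len(K)) {
    tr_x <- d$X[folds$x != i, , drop = FALSE]
    tr_y <- d$Y[folds$y != i, , drop = FALSE]
    ho_x <- d$X[folds$x == i, , drop = FALSE]
    ho_y <- d$Y[folds$y == i, , drop = FALSE]
    if (nrow(ho_x) == 0L || nrow(ho_y) == 0L)
      stop_validation("a fold is missing one class; reduce K or rebalance")
    betas <- if (fitter == "aucpr") {
      tr <- two_class_data(tr_x, tr_y, d$marker_ids)
      enet_path(compute_summary_stats(tr), lambdas, alpha,
                standardize = standardize)$beta
    } else {
      logistic_path(tr_x, tr_y, lambdas, alpha)
    }
    sx <- ho_x %*% betas
    sy <- ho_y %*% betas
    fold_auc[i, ] <- vapply(seq_along(lambdas), function(l)
      empirical_auc(sy[, l], sx[, l], ties = "strict"), numeric(1))
  }
  cv_scores <- colSums(fold_auc)
  sel <- which.max(cv_scores)  # candidates descending: first max = largest lambda
  structure(list(lambda = lambdas, cv_scores = cv_scores, fold_auc = fold_auc,
                 selected_lambda = lambdas[sel], selected_index = sel,
                 fold_x = folds$x, fold_y = folds$y, K = K, alpha = alpha,
                 fitter = fitter),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV over %d lambdas (%s fitter): selected lambda = %.4g (CV score %.3f of %d)\n",
              x$K, length(x$lambda), x$fitter, x$selected_lambda,
              max(x$cv_scores), x$K))
  invisible(x)
}

#' Fit the marker combination with cross-validated penalty strength
#'
#' Builds the candidate grid on the full data, selects lambda by
#' [cv_select()], and refits on all samples at the selected value.
#'
#' @inheritParams cv_select
#' @param complex_support support size of the densest grid endpoint.
#' @param n_candidates number of grid candidates.
#' @return A list with components `coef` (an `aucpr_coef`), `cv`
#'   (a `cv_result`) and `grid` (the `lambda_grid`).
#' @export
fit_aucpr_cv <- function(d, K = 3L, alpha = 0.5, complex_support = 100L,
                         n_candidates = 50L, seed = NULL, standardize = FALSE) {
  stopifnot(inherits(d, "two_class_data"))
  stats <- compute_summary_stats(d)
  grid <- make_lambda_grid(stats, complex_support, n_candidates, alpha,
                           standardize = standardize)
  cv <- cv_select(d, grid, K = K, alpha = alpha, seed = seed,
                  fitter = "aucpr", standardize = standardize)
  # Refit on the full data along the whole grid (warm-started); the final
  # coefficients are the path entry at the selected lambda, and the support
  # sizes along the path are kept for diagnostics.
  path <- enet_path(stats, grid$candidates, alpha, standardize = standardize)
  sel <- cv$selected_index
  coef_fit <- new_aucpr_coef(path$beta[, sel], stats$marker_ids,
                             cv$selected_lambda, alpha,
                             n_iter = path$iters[sel])
  cv$support_path <- colSums(abs(path$beta) > AUCPR_ZERO_TOL)
  list(coef = coef_fit, cv = cv, grid = grid)
}
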