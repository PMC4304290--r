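# Penalized logistic regression baseline (elastic net / lasso), fitted with
# glmnet.  Lambda is reported on the package's unscaled objective
#   -loglik(b0, b) + lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2),
# i.e. lambda = N * lambda_glmnet with N the number of training samples
# (glmnet averages the log-likelihood over samples).  The intercept is
# unpenalized and excluded from the returned coefficient vector, so support
# counts cover markers only.

# Coefficient matrix (p x length(lambdas), no intercept) along a descending
# lambda path on the package scale.
# glmnet refuses single-column designs; pad with an all-zero dummy (its
# coefficient is identically zero) and drop it afterwards.
pad_single_column <- function(xx) {
  if (ncol(xx) >= 2L) return(list(x = xx, padded = FALSE))
  list(x = cbind(xx, 0), padded = TRUE)
}

logistic_path <- function(X, Y, lambdas, alpha) {
  xx <- rbind(X, Y)
  yy <- c(rep(0L, nrow(X)), rep(1L, nrow(Y)))
  N <- nrow(xx)
  pad <- pad_single_column(xx)
  xx <- pad$x
  fit <- glmnet::glmnet(xx, yy, family = "binomial", alpha = alpha,
                        lambda = lambdas / N, standardize = TRUE)
  beta <- as.matrix(fit$beta)
  # glmnet can drop trailing path entries on early saturation; pad by reusing
  # the last fitted column (the path is monotone in lambda).
  if (ncol(beta) < length(lambdas)) {
    beta <- cbind(beta, beta[, rep(ncol(beta), length(lambdas) - ncol(beta)),
                             drop = FALSE])
  }
  if (pad$padded) beta <- beta[1L, , drop = FALSE]
  unname(beta)
}

#' Penalized logistic regression baseline
#'
#' Maximizes the binomial log-likelihood penalized by
#' \eqn{\lambda(\alpha\|\beta\|_1 + \frac{1-\alpha}{2}\|\beta\|_2^2)} over
#' the marker coefficients (intercept unpenalized).
#'
#' @param d a [two_class_data()] object.
#' @param lambda penalty strength on the unscaled (total log-likelihood)
#'   objective.
#' @param alpha elastic-net mixing parameter (1 = lasso).
#' @return An `aucpr_coef` object whose `beta` excludes the intercept; the
#'   fitted intercept is stored in the `intercept` element.
#' @export
fit_penalized_logistic <- function(d, lambda, alpha = 0.5) {
  stopifnot(inherits(d, "two_class_data"))
  if (lambda < 0) stop_validation("lambda must be nonnegative")
  xx <- rbind(d$X, d$Y)
  yy <- c(rep(0L, d$m), rep(1L, d$n))
  N <- nrow(xx)
  pad <- pad_single_column(xx)
  xx <- pad$x
  lam_g <- lambda / N
  # Fit along a short descending path ending at the requested lambda so the
  # coordinate solver is warm-started (glmnet's recommended usage).
  lam_top <- max(lam_g * 100, lam_g + 1e-8)
  lam_seq <- unique(exp(seq(log(lam_top), log(max(lam_g, 1e-12)),
                            length.out = 25L)))
  fit <- glmnet::glmnet(xx, yy, family = "binomial", alpha = alpha,
                        lambda = lam_seq, standardize = TRUE)
  j <- ncol(fit$beta)
  slopes <- as.numeric(fit$beta[, j])
  if (pad$padded) slopes <- slopes[1L]
  new_aucpr_coef(slopes, d$marker_ids, lambda, alpha, intercept = fit$a0[j])
}

# Candidate grid for the logistic baseline: glmnet's own data-driven lambda
# range on the full training data, log-even with n_candidates points,
# converted to the package's unscaled objective.  Mirrors the
# fixed-grid-on-full-data convention used for the covariance regression.
logistic_lambda_grid <- function(d, alpha = 0.5, n_candidates = 50L) {
  xx <- pad_single_column(rbind(d$X, d$Y))$x
  yy <- c(rep(0L, d$m), rep(1L, d$n))
  N <- nrow(xx)
  fit <- glmnet::glmnet(xx, yy, family = "binomial", alpha = alpha,
                        nlambda = 20L, standardize = TRUE)
  rng <- range(fit$lambda) * N
  candidates <- exp(seq(log(rng[2]), log(rng[1]), length.out = n_candidates))
  structure(list(lambda_l = rng[1], lambda_u = rng[2],
                 candidates = candidates,
                 n_candidates = as.integer(n_candidates), alpha = alpha,
                 support_l = NA_integer_, support_u = NA_integer_),
            class = "lambda_grid")
}
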