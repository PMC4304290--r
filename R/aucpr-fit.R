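#' Fit an AUC-maximizing sparse marker combination
#'
#' Main front-end.  Splits the samples into cases (label 1) and controls
#' (label 0), computes the class summary statistics, and fits the penalized
#' covariance regression.  When `lambda` is `NULL` (default) the penalty
#' strength is tuned by stratified K-fold cross-validation maximizing the
#' summed empirical AUC of the held-out folds over a log-even candidate grid;
#' otherwise a single fit at the given `lambda` is returned.
#'
#' @param x numeric matrix, samples in rows and markers in columns (or a
#'   [two_class_data()] object, in which case `labels` is ignored).
#' @param labels per-sample binary status, 1 = diseased/case (the score-high
#'   class), 0 = non-diseased/control.
#' @param alpha elastic-net mixing parameter; 0.5 by default, 1 gives the
#'   lasso.
#' @param lambda optional fixed penalty strength (skips cross-validation).
#' @param nfolds cross-validation folds (default 3).
#' @param complex_support support size of the densest candidate model
#'   (default 100, capped at `min(p, m + n - 2)`).
#' @param n_candidates number of lambda candidates (default 50).
#' @param seed integer seed for the fold shuffle.
#' @param standardize rescale the covariance design columns to unit RMS
#'   before penalization (sensitivity option; default `FALSE` solves the
#'   objective exactly as posed).
#' @return An object of class `aucpr`: list with `coefficients` (named
#'   numeric), `support` (nonzero indices), `lambda`, `alpha`, `cv` (a
#'   `cv_result`, or `NULL` for fixed-lambda fits), `grid`, `stats_dim`
#'   (m, n, p), `marker_ids`, `call`.
#' @examples
#' set.seed(1)
#' sim <- generate_normal_scenario(sim_config(block_size = 5, p_total = 50,
#'                                            seed = 1))
#' fit <- aucpr(sim$train, seed = 1)
#' print(fit)
#' head(coef(fit)[fit$support])
#' auc_test <- empirical_auc(predict(fit, sim$test$Y),
#'                           predict(fit, sim$test$X))
#' @export
aucpr <- function(x, labels = NULL, alpha = 0.5, lambda = NULL, nfolds = 3L,
                  complex_support = 100L, n_candidates = 50L, seed = NULL,
                  standardize = FALSE) {
  cl <- match.call()
  d <- if (inherits(x, "two_class_data")) {
    x
  } else {
    if (is.null(labels))
      stop_validation("labels are required when x is a plain matrix")
    as_two_class(expression_table(as.matrix(x), labels))
  }
  if (is.null(lambda)) {
    fit <- fit_aucpr_cv(d, K = nfolds, alpha = alpha,
                        complex_support = complex_support,
                        n_candidates = n_candidates, seed = seed,
                        standardize = standardize)
    coef_fit <- fit$coef; cv <- fit$cv; grid <- fit$grid
  } else {
    stats <- compute_summary_stats(d)
    coef_fit <- fit_aucpr(stats, lambda, alpha, standardize = standardize)
    cv <- NULL; grid <- NULL
  }
  structure(list(coefficients = coef_fit$beta, support = coef_fit$support,
                 lambda = coef_fit$lambda, alpha = alpha, cv = cv,
                 grid = grid, stats_dim = c(m = d$m, n = d$n, p = d$p),
                 marker_ids = d$marker_ids, standardize = standardize,
                 call = cl),
            class = "aucpr")
}

#' @export
print.aucpr <- function(x, ...) {
  cat("AUC-maximizing penalized marker combination\n")
  cat(sprintf("  %d markers, %d controls + %d cases\n",
              x$stats_dim["p"], x$stats_dim["m"], x$stats_dim["n"]))
  cat(sprintf("  alpha = %.2f, lambda = %.4g (%s), support = %d markers\n",
              x$alpha, x$lambda,
              if (is.null(x$cv)) "fixed" else
                sprintf("%d-fold AUC-CV", x$cv$K),
              length(x$support)))
  invisible(x)
}

#' @export
coef.aucpr <- function(object, ...) object$coefficients

#' @rdname aucpr
#' @param object,newdata an `aucpr` fit and a samples x markers matrix.
#' @param ... unused.
#' @export
predict.aucpr <- function(object, newdata, ...) {
  score_samples(object$coefficients, newdata)
}

#' @export
summary.aucpr <- function(object, ...) {
  sup <- object$support
  top <- sup[order(-abs(object$coefficients[sup]))]
  structure(list(fit = object,
                 top_markers = object$coefficients[head(top, 10L)],
                 cv_score = if (!is.null(object$cv))
                   max(object$cv$cv_scores) else NA_real_),
            class = "summary.aucpr")
}

#' @export
print.summary.aucpr <- function(x, ...) {
  print(x$fit)
  if (!is.na(x$cv_score))
    cat(sprintf("  best CV score: %.3f (sum of %d fold AUCs)\n",
                x$cv_score, x$fit$cv$K))
  cat("  largest coefficients:\n")
  print(round(x$top_markers, 4))
  invisible(x)
}

#' @export
plot.aucpr <- function(x, ...) {
  if (is.null(x$cv))
    stop_validation("nothing to plot: the model was fit at a fixed lambda")
  graphics::plot(log(x$cv$lambda), x$cv$cv_scores, type = "b", pch = 19,
                 cex = 0.6, xlab = expression(log(lambda)),
                 ylab = sprintf("CV score (sum of %d fold AUCs)", x$cv$K),
                 ...)
  graphics::abline(v = log(x$lambda), lty = 2)
  invisible(x)
}
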