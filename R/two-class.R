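#' Two-class sample container
#'
#' Holds the non-diseased (control) sample matrix `X` (m x p) and the diseased
#' (case) sample matrix `Y` (n x p) over a common set of p markers.  The class
#' coded 1 in label vectors is "diseased" and is always the score-high class,
#' which fixes the sign of the mean difference \eqn{\hat\mu = \hat\mu_y -
#' \hat\mu_x}.
#'
#' @param X numeric matrix of non-diseased samples, one row per sample.
#' @param Y numeric matrix of diseased samples, one row per sample.
#' @param marker_ids optional character vector of marker identifiers; defaults
#'   to the column names of `X`/`Y` or `m1..mp`.
#' @return An object of class `two_class_data`: a list with elements `X`, `Y`,
#'   `marker_ids`, `m` (controls), `n` (cases), `p`.
#' @export
two_class_data <- function(X, Y, marker_ids = NULL) {
  make_two_class(X, Y, marker_ids, min_per_class = 2L)
}

# Internal constructor; test-set containers (scoring only) may hold a single
# sample per class, while anything feeding compute_summary_stats needs 2.
make_two_class <- function(X, Y, marker_ids = NULL, min_per_class = 2L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!is.numeric(X) || !is.numeric(Y))
    stop_validation("X and Y must be numeric matrices")
  if (ncol(X) != ncol(Y))
    stop_validation("X and Y must share the same markers (equal column count)")
  if (nrow(X) < min_per_class || nrow(Y) < min_per_class)
    stop_validation(sprintf("each class needs at least %d sample(s)",
                            min_per_class))
  if (anyNA(X) || anyNA(Y))
    stop_validation("missing values are not allowed")
  if (is.null(marker_ids)) marker_ids <- colnames(X) %||% colnames(Y)
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(ncol(X)))
  if (anyDuplicated(marker_ids))
    stop_validation("marker_ids must be unique")
  colnames(X) <- colnames(Y) <- marker_ids
  structure(list(X = X, Y = Y, marker_ids = as.character(marker_ids),
                 m = nrow(X), n = nrow(Y), p = ncol(X)),
            class = "two_class_data")
}

#' @export
print.two_class_data <- function(x, ...) {
  cat(sprintf("Two-class data: %d non-diseased + %d diseased samples, %d markers\n",
              x$m, x$n, x$p))
  invisible(x)
}

#' Per-class summary statistics for the AUC-optimal combination
#'
#' Computes the per-class marker means and sample covariance matrices (with
#' m-1 / n-1 denominators), the mean-difference vector
#' \eqn{\hat\mu = \hat\mu_y - \hat\mu_x} and the pooled covariance
#' \eqn{\hat\Sigma = \hat\Sigma_y + \hat\Sigma_x} that define the penalized
#' regression problem.
#'
#' @param d a [two_class_data()] object.
#' @return An object of class `aucpr_stats`: list with `mu_x`, `mu_y`,
#'   `sigma_x`, `sigma_y`, `mu_diff`, `sigma_sum`, `m`, `n`, `p`,
#'   `marker_ids`.
#' @examples
#' d <- two_class_data(X = rbind(c(0, 0), c(2, 2)),
#'                     Y = rbind(c(1, 3), c(3, 5)))
#' s <- compute_summary_stats(d)
#' s$mu_diff   # (1, 3)
#' @export
compute_summary_stats <- function(d) {
  stopifnot(inherits(d, "two_class_data"))
  if (d$m < 2L || d$n < 2L)
    stop_validation("each class needs at least 2 samples for sample covariances")
  mu_x <- colMeans(d$X)
  mu_y <- colMeans(d$Y)
  sigma_x <- stats::cov(d$X)
  sigma_y <- stats::cov(d$Y)
  structure(list(mu_x = mu_x, mu_y = mu_y,
                 sigma_x = sigma_x, sigma_y = sigma_y,
                 mu_diff = mu_y - mu_x,
                 sigma_sum = sigma_x + sigma_y,
                 m = d$m, n = d$n, p = d$p,
                 marker_ids = d$marker_ids),
            class = "aucpr_stats")
}

#' @export
print.aucpr_stats <- function(x, ...) {
  cat(sprintf("Summary statistics: p = %d markers, m = %d controls, n = %d cases\n",
              x$p, x$m, x$n))
  invisible(x)
}
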