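# Empirical ROC metrics by pair counting.  The AUC estimator is the
# Mann-Whitney fraction sum_i sum_j I(s_y[i] > s_x[j]) / (n m); "strict" is
# the default (ties count as misorderings), "half" credits tied pairs 0.5.

#' Empirical AUC by pair counting
#'
#' @param scores_y numeric scores of the diseased (case) samples.
#' @param scores_x numeric scores of the non-diseased (control) samples.
#' @param ties `"strict"` (default; tied pairs count 0) or `"half"` (tied
#'   pairs count 0.5, the Mann-Whitney convention).
#' @return The empirical AUC in \[0, 1\].
#' @examples
#' empirical_auc(c(2, 1), c(1.5, 0.5))           # 3/4
#' empirical_auc(rep(1, 3), rep(1, 4))            # 0 (strict)
#' empirical_auc(rep(1, 3), rep(1, 4), "half")    # 0.5
#' @export
empirical_auc <- function(scores_y, scores_x, ties = c("strict", "half")) {
  ties <- match.arg(ties)
  if (length(scores_y) == 0L || length(scores_x) == 0L)
    stop_validation("both score vectors must be nonempty")
  sxs <- sort(scores_x)
  n_lt <- findInterval(scores_y, sxs, left.open = TRUE)  # x <  y counts
  if (ties == "strict") return(sum(n_lt) / (length(scores_y) * length(scores_x)))
  n_le <- findInterval(scores_y, sxs)                    # x <= y counts
  (sum(n_lt) + 0.5 * sum(n_le - n_lt)) /
    (length(scores_y) * length(scores_x))
}

#' Empirical ROC curve
#'
#' Sweeps the decision rule "score > threshold => diseased" over all distinct
#' observed scores.  The returned coordinates start at (0, 0) (threshold above
#' all scores) and end at (1, 1).  The area under the curve, integrating the
#' piecewise-linear path through the returned vertices, equals
#' `empirical_auc(..., ties = "half")`; with tie-free scores the path is a
#' staircase and the area is the plain step integral.
#'
#' @inheritParams empirical_auc
#' @return An object of class `roc_curve`: list with `thresholds` (descending,
#'   starting at `Inf`), `sensitivity` and `one_minus_specificity`
#'   (nondecreasing), and `auc` (the half-tie empirical AUC).
#' @export
roc_curve <- function(scores_y, scores_x) {
  if (length(scores_y) == 0L || length(scores_x) == 0L)
    stop_validation("both score vectors must be nonempty")
  thr <- c(Inf, sort(unique(c(scores_y, scores_x)), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t) mean(scores_y > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores_x > t), numeric(1))
  structure(list(thresholds = thr, sensitivity = sens,
                 one_minus_specificity = fpr,
                 auc = empirical_auc(scores_y, scores_x, ties = "half")),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC curve: %d thresholds, AUC (half-tie) = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$one_minus_specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# Area under the vertex path of a roc_curve (trapezoids between vertices;
# axis-aligned segments make this the step integral for tie-free scores).
roc_auc_step <- function(curve) {
  fpr <- curve$one_minus_specificity
  sens <- curve$sensitivity
  sum(diff(fpr) * (head(sens, -1) + sens[-1]) / 2)
}

#' Sensitivity at a fixed specificity
#'
#' Chooses the threshold t* as the smallest observed control-score order
#' statistic with empirical specificity (fraction of control scores <= t*) at
#' least `target_spec`, then returns the fraction of case scores above t*.
#' No interpolation is used: with m = 20 controls and `target_spec = 0.95`,
#' t* is the 19th order statistic of the control scores.
#'
#' @inheritParams empirical_auc
#' @param target_spec required specificity, strictly between 0 and 1.
#' @return The empirical sensitivity in \[0, 1\].
#' @export
sensitivity_at_specificity <- function(scores_y, scores_x, target_spec = 0.95) {
  if (length(scores_y) == 0L || length(scores_x) == 0L)
    stop_validation("both score vectors must be nonempty")
  if (target_spec <= 0 || target_spec >= 1)
    stop_validation("target_spec must be strictly between 0 and 1")
  sxs <- sort(scores_x)
  k <- ceiling(target_spec * length(sxs))
  t_star <- sxs[k]
  mean(scores_y > t_star)
}
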