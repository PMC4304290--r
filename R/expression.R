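# Expression-table I/O and preprocessing: delimited-text reading with strict
# missing-value handling, quantile normalization across samples, log
# transformation, moderated-t / ordinary-t marker screening, and stratified
# train/test splitting.

#' Expression table constructor
#'
#' @param values numeric matrix, samples in rows and markers in columns.
#' @param labels per-sample binary disease status (1 = diseased/case,
#'   0 = non-diseased/control).
#' @param marker_ids,sample_ids identifiers; default to dimnames.
#' @return An object of class `expr_table`: list with `values`, `labels`,
#'   `marker_ids`, `sample_ids`.
#' @export
expression_table <- function(values, labels, marker_ids = NULL,
                             sample_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_validation("expression values must be numeric")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop_validation(sprintf("missing value at sample '%s', marker '%s'",
                            (rownames(values) %||% seq_len(nrow(values)))[bad[1L]],
                            (colnames(values) %||% seq_len(ncol(values)))[bad[2L]]))
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop_validation("labels must have one entry per sample")
  if (!all(labels %in% c(0L, 1L)))
    stop_validation("labels must be coded 0 (control) / 1 (case)")
  marker_ids <- as.character(marker_ids %||% colnames(values) %||%
                               paste0("m", seq_len(ncol(values))))
  sample_ids <- as.character(sample_ids %||% rownames(values) %||%
                               paste0("s", seq_len(nrow(values))))
  if (anyDuplicated(marker_ids)) {
    stop_validation(sprintf("duplicate marker id: '%s'",
                            marker_ids[anyDuplicated(marker_ids)]))
  }
  if (anyDuplicated(sample_ids))
    stop_validation("sample ids must be unique")
  dimnames(values) <- list(sample_ids, marker_ids)
  structure(list(values = values, labels = labels, marker_ids = marker_ids,
                 sample_ids = sample_ids),
            class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat(sprintf("Expression table: %d samples x %d markers (%d cases, %d controls)\n",
              nrow(x$values), ncol(x$values), sum(x$labels == 1L),
              sum(x$labels == 0L)))
  invisible(x)
}

#' Read a delimited expression table with binary labels
#'
#' Reads a TSV/CSV file with a header line.  With
#' `orientation = "markers-in-columns"` rows are samples (first column =
#' sample id) and columns are markers; with `"markers-in-rows"` rows are
#' markers (first column = marker id) and columns are samples.  Labels come
#' either from a column of the table (markers-in-columns only) or from a
#' separate two-column file (sample_id, label).  Label values are mapped to
#' 0/1 through `label_map` (e.g. `c(control = 0, case = 1)`); raw 0/1 labels
#' need no map.
#'
#' @param path path to the expression file.
#' @param orientation `"markers-in-columns"` (default) or `"markers-in-rows"`.
#' @param label_source name of the label column, or path to a label file.
#' @param label_map named vector mapping the two label codes to 0 and 1.
#' @param sep field separator; inferred from the file extension by default.
#' @return An [expression_table()] in samples x markers orientation.
#' @export
read_expression <- function(path, orientation = c("markers-in-columns",
                                                  "markers-in-rows"),
                            label_source, label_map = NULL, sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  sep <- sep %||% (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  label_is_file <- file.exists(label_source) && !label_source %in% colnames(raw)
  labels_raw <- NULL
  if (!label_is_file) {
    if (orientation == "markers-in-rows")
      stop_validation("with markers-in-rows, labels must come from a separate file")
    if (!label_source %in% colnames(raw))
      stop_validation(sprintf("label column '%s' not found", label_source))
    labels_raw <- raw[[label_source]]
    names(labels_raw) <- rownames(raw)
    raw <- raw[, setdiff(colnames(raw), label_source), drop = FALSE]
  }
  # strict numeric conversion with cell-level error reporting
  values <- matrix(NA_real_, nrow(raw), ncol(raw),
                   dimnames = list(rownames(raw), colnames(raw)))
  for (j in seq_len(ncol(raw))) {
    col <- raw[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      what <- if (is.na(col[bad[1L]]) || !nzchar(trimws(col[bad[1L]])))
        "missing value" else sprintf("non-numeric value '%s'", col[bad[1L]])
      stop_validation(sprintf("%s at row '%s', column '%s'",
                              what, rownames(raw)[bad[1L]], colnames(raw)[j]))
    }
    values[, j] <- num
  }
  if (orientation == "markers-in-rows") values <- t(values)
  if (label_is_file) {
    lab_tab <- utils::read.table(label_source, header = TRUE, sep = sep,
                                 check.names = FALSE, colClasses = "character")
    if (ncol(lab_tab) < 2L)
      stop_validation("label file must have two columns: sample_id, label")
    labels_raw <- lab_tab[[2L]]
    names(labels_raw) <- lab_tab[[1L]]
    missing <- setdiff(rownames(values), names(labels_raw))
    if (length(missing))
      stop_validation(sprintf("no label for sample(s): %s",
                              paste(missing, collapse = ", ")))
    labels_raw <- labels_raw[rownames(values)]
  }
  if (!is.null(label_map)) {
    unknown <- setdiff(unique(labels_raw), names(label_map))
    if (length(unknown))
      stop_validation(sprintf("label value(s) not in label_map: %s",
                              paste(unknown, collapse = ", ")))
    labels <- as.integer(label_map[labels_raw])
  } else {
    labels <- suppressWarnings(as.integer(labels_raw))
    if (anyNA(labels) || !all(labels %in% 0:1))
      stop_validation("labels are not 0/1; supply label_map to recode them")
  }
  if (length(unique(labels)) < 2L)
    stop_validation("labels contain a single class; both classes are required")
  expression_table(values, labels)
}

#' Quantile normalization across samples
#'
#' Forces every sample's empirical distribution to the across-sample mean of
#' the order statistics (standard quantile normalization); marker and sample
#' identities are preserved.
#'
#' @param t an [expression_table()].
#' @return The normalized `expr_table`.
#' @export
quantile_normalize <- function(t) {
  stopifnot(inherits(t, "expr_table"))
  if (nrow(t$values) < 2L)
    stop_validation("quantile normalization needs at least 2 samples")
  if (any(!is.finite(t$values)))
    stop_validation("all values must be finite")
  # limma normalizes columns = samples, so transpose in and out
  norm <- t(limma::normalizeQuantiles(t(t$values)))
  dimnames(norm) <- dimnames(t$values)
  expression_table(norm, t$labels, t$marker_ids, t$sample_ids)
}

#' Elementwise log transformation
#'
#' @param t an [expression_table()].
#' @param base 2 (default) or `exp(1)`.
#' @param offset nonnegative scalar added before taking logs.
#' @return The transformed `expr_table`.
#' @export
log_transform <- function(t, base = 2, offset = 0) {
  stopifnot(inherits(t, "expr_table"))
  if (offset < 0) stop_validation("offset must be nonnegative")
  shifted <- t$values + offset
  n_bad <- sum(shifted <= 0)
  if (n_bad > 0L)
    stop_validation(sprintf("%d value(s) are nonpositive after adding offset %g",
                            n_bad, offset))
  expression_table(log(shifted, base = base), t$labels, t$marker_ids,
                   t$sample_ids)
}

# Pooled-variance two-sample t per marker; zero-variance markers get
# |t| = Inf when the mean difference is nonzero and 0 otherwise, so the
# ranking stays deterministic.
ordinary_t_stats <- function(values, labels) {
  x <- values[labels == 0L, , drop = FALSE]
  y <- values[labels == 1L, , drop = FALSE]
  m <- nrow(x); n <- nrow(y)
  diff <- colMeans(y) - colMeans(x)
  ssx <- colSums(sweep(x, 2L, colMeans(x))^2)
  ssy <- colSums(sweep(y, 2L, colMeans(y))^2)
  s2 <- (ssx + ssy) / (m + n - 2)
  se <- sqrt(s2 * (1 / m + 1 / n))
  t_stat <- ifelse(se > 0, diff / se, ifelse(diff != 0, Inf * sign(diff), 0))
  t_stat
}

moderated_t_stats <- function(values, labels) {
  design <- cbind(Intercept = 1, group = labels)
  fit <- limma::eBayes(limma::lmFit(t(values), design))
  fit$t[, "group"]
}

#' Screen markers by largest absolute t-type statistic
#'
#' Keeps the `k` markers with the largest absolute moderated t-statistic
#' (empirical-Bayes shrunken variance, via limma) or ordinary pooled-variance
#' two-sample t-statistic, in their original relative order.
#'
#' @param t an [expression_table()] with both classes present.
#' @param k number of markers to keep.
#' @param statistic `"moderated_t"` (default) or `"ordinary_t"`.
#' @return The screened `expr_table`; the named statistic vector of the kept
#'   markers is attached as attribute `"statistic"`.
#' @export
screen_markers <- function(t, k, statistic = c("moderated_t", "ordinary_t")) {
  stopifnot(inherits(t, "expr_table"))
  statistic <- match.arg(statistic)
  k <- as.integer(k)
  if (k < 1L || k > ncol(t$values))
    stop_validation(sprintf("k must be between 1 and the number of markers (%d)",
                            ncol(t$values)))
  if (length(unique(t$labels)) < 2L)
    stop_validation("both classes are required for screening")
  stat <- switch(statistic,
                 moderated_t = moderated_t_stats(t$values, t$labels),
                 ordinary_t = ordinary_t_stats(t$values, t$labels))
  keep <- sort(order(-abs(stat), seq_along(stat))[seq_len(k)])
  out <- expression_table(t$values[, keep, drop = FALSE], t$labels,
                          t$marker_ids[keep], t$sample_ids)
  attr(out, "statistic") <- stats::setNames(stat[keep], t$marker_ids[keep])
  out
}

#' Stratified random train/test split
#'
#' Splits each class separately: `floor(train_fraction * class size)` samples
#' go to the training set, the remainder to the test set.  The same seed
#' always reproduces the same split.
#'
#' @param t an [expression_table()].
#' @param train_fraction fraction of each class assigned to training.
#' @param seed integer seed (optional).
#' @return A list with `train` and `test`, both [two_class_data()] objects;
#'   the selected sample ids are attached as attributes `train_ids` and
#'   `test_ids`.
#' @export
split_train_test <- function(t, train_fraction = 2 / 3, seed = NULL) {
  stopifnot(inherits(t, "expr_table"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_validation("train_fraction must be strictly between 0 and 1")
  idx0 <- which(t$labels == 0L)
  idx1 <- which(t$labels == 1L)
  pick <- with_seed(seed, {
    list(tr0 = sort(sample(idx0, floor(train_fraction * length(idx0)))),
         tr1 = sort(sample(idx1, floor(train_fraction * length(idx1)))))
  })
  te0 <- setdiff(idx0, pick$tr0)
  te1 <- setdiff(idx1, pick$tr1)
  if (min(lengths(pick)) < 2L || length(te0) < 1L || length(te1) < 1L)
    stop_validation("a class is too small to appear in both train and test")
  train <- two_class_data(t$values[pick$tr0, , drop = FALSE],
                          t$values[pick$tr1, , drop = FALSE], t$marker_ids)
  test <- make_two_class(t$values[te0, , drop = FALSE],
                         t$values[te1, , drop = FALSE], t$marker_ids,
                         min_per_class = 1L)
  attr(train, "train_ids") <- t$sample_ids[sort(c(pick$tr0, pick$tr1))]
  attr(test, "test_ids") <- t$sample_ids[sort(c(te0, te1))]
  list(train = train, test = test)
}

#' Convert an expression table to a two-class container
#'
#' @param t an [expression_table()].
#' @return A [two_class_data()] with controls as `X` and cases as `Y`.
#' @export
as_two_class <- function(t) {
  stopifnot(inherits(t, "expr_table"))
  two_class_data(t$values[t$labels == 0L, , drop = FALSE],
                 t$values[t$labels == 1L, , drop = FALSE], t$marker_ids)
}
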