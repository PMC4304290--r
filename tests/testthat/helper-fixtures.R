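# Shared fixtures, all generated in code.

# Well-conditioned random two-class data: p markers, n_per samples per class,
# cases shifted by `shift` on every marker.
toy_two_class <- function(p = 10, n_per = 30, shift = 0.3, seed = 42) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed(two_class_data(matrix(rnorm(n_per * p), n_per),
                            matrix(rnorm(n_per * p, shift), n_per)))
}

# The hand-computable 2x2 example: X rows {(0,0),(2,2)}, Y rows {(1,3),(3,5)}.
hand_two_class <- function() {
  two_class_data(X = rbind(c(0, 0), c(2, 2)),
                 Y = rbind(c(1, 3), c(3, 5)),
                 marker_ids = c("g1", "g2"))
}

# Small labelled expression table (values drawn deterministically).
toy_expr_table <- function(n_per = 6, p = 8, shift = 2, seed = 7) {
  set.seed(seed)
  values <- rbind(matrix(rnorm(n_per * p), n_per),
                  matrix(rnorm(n_per * p, shift), n_per))
  expression_table(values, labels = rep(c(0L, 1L), each = n_per))
}

# Write an expression table as a TSV with a label column; returns the path.
write_expr_tsv <- function(tab, path = tempfile(fileext = ".tsv"),
                           label_codes = c("control", "case")) {
  df <- data.frame(sample_id = tab$sample_ids,
                   tab$values,
                   status = label_codes[tab$labels + 1L],
                   check.names = FALSE)
  colnames(df) <- c("sample_id", tab$marker_ids, "status")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Brute-force empirical AUC by an explicit double loop over pairs.
brute_auc <- function(sy, sx, ties = "strict") {
  tot <- 0
  for (a in sy) for (b in sx) {
    if (a > b) tot <- tot + 1
    else if (a == b && ties == "half") tot <- tot + 0.5
  }
  tot / (length(sy) * length(sx))
}
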