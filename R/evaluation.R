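# Q3 accuracy, confusion matrices and per-protein histograms.

#' Q3 accuracy of an assignment
#'
#' Fraction of residues whose three-state label matches the reference.
#'
#' @param pred,truth Label strings (or letter vectors) of equal, positive
#'   length.
#' @return A fraction in \[0, 1\].
#' @export
q3 <- function(pred, truth) {
  p <- ss_chars(pred); t <- ss_chars(truth)
  if (length(p) == 0L || length(t) == 0L) abort("alignment error: empty assignment")
  if (length(p) != length(t)) abort("alignment error: prediction and truth differ in length")
  mean(p == t)
}

#' Row-normalized confusion matrix
#'
#' Entry (t, p) is the percentage of residues with true class t predicted as
#' class p; each row with at least one true residue sums to 100. A class
#' absent from the truth yields an `NA` row.
#'
#' @param pred,truth Label strings (or letter vectors) of equal length.
#' @return 3 x 3 numeric matrix of percentages, rows/columns H, E, C.
#' @export
confusion_matrix <- function(pred, truth) {
  p <- ss_chars(pred); t <- ss_chars(truth)
  if (length(p) != length(t)) abort("alignment error: prediction and truth differ in length")
  tab <- table(factor(t, ss_alphabet), factor(p, ss_alphabet))
  m <- matrix(as.numeric(tab), 3, 3, dimnames = list(true = ss_alphabet, pred = ss_alphabet))
  rs <- rowSums(m)
  out <- 100 * m / ifelse(rs == 0, NA_real_, rs)
  out
}

#' Histogram of per-protein Q3 values
#'
#' Bins run over \[0, 100\] percent, 2.5 points wide by default, left-open
#' and right-closed (the bottom bin also includes 0), so a chain at exactly
#' 95.0% falls in the 92.5-95.0 bin.
#'
#' @param per_protein_q3 Numeric vector of Q3 fractions in \[0, 1\].
#' @param bin_width Bin width in percentage points.
#' @return Tibble with `bin_start`, `bin_end` (percent) and `count`.
#' @export
q3_histogram <- function(per_protein_q3, bin_width = 2.5) {
  if (any(per_protein_q3 < 0 | per_protein_q3 > 1)) abort("Q3 values must lie in [0, 1]")
  brk <- seq(0, 100, by = bin_width)
  if (brk[length(brk)] < 100) brk <- c(brk, 100)
  bins <- cut(100 * per_protein_q3, breaks = brk, include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(bins))
  tibble(bin_start = brk[-length(brk)], bin_end = brk[-1], count = counts)
}

#' Aggregate evaluation report over a set of chains
#'
#' Computes the residue-weighted Q3 over the concatenated chains, the
#' row-normalized confusion matrix, per-protein Q3 values and the number of
#' perfectly assigned chains.
#'
#' @param pred,truth Lists (or named character vectors) of aligned label
#'   strings; names, when present, are matched.
#' @return An `ss_eval` object with fields `q3`, `confusion`,
#'   `per_protein_q3`, `n_perfect`, `n_residues`.
#' @export
eval_report <- function(pred, truth) {
  pred <- as.list(pred); truth <- as.list(truth)
  if (!is.null(names(pred)) && !is.null(names(truth)) &&
      all(nzchar(names(pred))) && all(nzchar(names(truth)))) {
    shared <- intersect(names(pred), names(truth))
    if (!length(shared)) abort("no overlapping chain identifiers")
    pred <- pred[shared]; truth <- truth[shared]
  }
  if (length(pred) != length(truth)) abort("prediction and truth sets differ in size")
  per <- purrr::map2_dbl(pred, truth, q3)
  all_p <- unlist(lapply(pred, ss_chars), use.names = FALSE)
  all_t <- unlist(lapply(truth, ss_chars), use.names = FALSE)
  structure(
    list(
      q3 = mean(all_p == all_t),
      confusion = confusion_matrix(all_p, all_t),
      per_protein_q3 = per,
      n_perfect = sum(per == 1),
      n_residues = length(all_t),
      n_chains = length(per)
    ),
    class = "ss_eval"
  )
}

#' Per-class recall of an evaluation
#'
#' @param report An `ss_eval` object.
#' @return Named numeric vector of recalls (diagonal of the confusion
#'   matrix, as fractions) for H, E, C.
#' @export
class_recall <- function(report) {
  diag(report$confusion) / 100
}

#' @export
print.ss_eval <- function(x, ...) {
  cat(sprintf("<ss_eval> %d chains, %d residues\n", x$n_chains, x$n_residues))
  cat(sprintf("  Q3 (residue-weighted): %.4f\n", x$q3))
  cat(sprintf("  perfectly assigned chains: %d\n", x$n_perfect))
  cat("  confusion (% of true class):\n")
  print(round(x$confusion, 2))
  invisible(x)
}

#' Per-protein rows of an evaluation report
#'
#' @param x An `ss_eval`.
#' @param ... Unused.
#' @return Tibble with `chain` and `q3` per evaluated chain.
#' @method tidy ss_eval
#' @export
tidy.ss_eval <- function(x, ...) {
  nm <- names(x$per_protein_q3)
  tibble(
    chain = if (is.null(nm)) as.character(seq_along(x$per_protein_q3)) else nm,
    q3 = unname(x$per_protein_q3)
  )
}

#' One-row summary of an evaluation report
#'
#' @param x An `ss_eval`.
#' @param ... Unused.
#' @method glance ss_eval
#' @export
glance.ss_eval <- function(x, ...) {
  rec <- class_recall(x)
  tibble(
    q3 = x$q3, n_chains = x$n_chains, n_residues = x$n_residues,
    n_perfect = x$n_perfect,
    recall_H = rec[["H"]], recall_E = rec[["E"]], recall_C = rec[["C"]]
  )
}

#' Histogram plot of per-protein Q3
#'
#' @param object An `ss_eval`.
#' @param bin_width Bin width in percentage points.
#' @param ... Unused.
#' @method autoplot ss_eval
#' @export
autoplot.ss_eval <- function(object, bin_width = 2.5, ...) {
  h <- q3_histogram(object$per_protein_q3, bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_start + bin_width / 2, y = .data$count)) +
    ggplot2::geom_col(width = bin_width * 0.92, fill = "grey35") +
    ggplot2::labs(x = "Per-protein Q3 (%)", y = "Chains") +
    ggplot2::theme_minimal()
}

#' Render an evaluation report to files
#'
#' Writes a JSON-like summary, the confusion matrix as TSV and the Q3
#' histogram as two-column TSV.
#'
#' @param report An `ss_eval`.
#' @param prefix Output path prefix.
#' @return Invisibly, the written paths.
#' @export
write_eval_report <- function(report, prefix) {
  summary_path <- paste0(prefix, "_summary.json")
  conf_path <- paste0(prefix, "_confusion.tsv")
  hist_path <- paste0(prefix, "_histogram.tsv")
  jsonlite::write_json(
    list(q3 = report$q3, n_chains = report$n_chains, n_residues = report$n_residues,
         n_perfect = report$n_perfect, per_protein_q3 = report$per_protein_q3),
    summary_path, auto_unbox = TRUE, digits = NA
  )
  conf <- cbind(true = rownames(report$confusion),
                as.data.frame(round(report$confusion, 4)))
  write.table(conf, conf_path, sep = "\t", quote = FALSE, row.names = FALSE)
  h <- q3_histogram(report$per_protein_q3)
  write.table(h[, c("bin_start", "count")], hist_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(summary_path, conf_path, hist_path))
}
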