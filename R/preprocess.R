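#' Quantile-normalize an expression matrix
#'
#' Forces every time-point column to share one reference distribution (the
#' per-rank means of the column-sorted matrix) while preserving each
#' column's within-column ranks, the usual preparation before perturbation
#' scoring so that no time point dominates simply through a shifted
#' intensity distribution.
#'
#' Ties within a column receive the mean of the reference values at their
#' tied ranks ("average ties"), which keeps the transform deterministic.
#' The operation is idempotent.
#'
#' @param mat numeric gene x time-point matrix with dimnames.
#' @return a matrix of the same dimensions and dimnames whose columns are
#'   permutations of one shared value multiset.
#' @export
quantile_normalize <- function(mat) {
  validate_expression_matrix(mat, allow_duplicates = TRUE)
  n <- nrow(mat)
  p <- ncol(mat)
  sorted <- matrix(0, n, p)
  for (j in seq_len(p)) sorted[, j] <- sort(mat[, j])
  ref <- rowMeans(sorted)
  out <- mat
  for (j in seq_len(p)) {
    o <- order(mat[, j])
    xs <- mat[o, j]
    tie_group <- cumsum(c(TRUE, diff(xs) != 0))
    out[o, j] <- stats::ave(ref, tie_group)
  }
  out
}

#' Collapse duplicate gene rows
#'
#' Array platforms often carry several probes per gene; this combines all
#' rows sharing a gene id into one, column-wise, keeping first-occurrence
#' row order.
#'
#' @param mat numeric matrix, possibly with repeated rownames.
#' @param method `"mean"` (default) or `"max"`.
#' @return a matrix with one row per distinct gene id.
#' @export
collapse_duplicate_genes <- function(mat, method = c("mean", "max")) {
  method <- match.arg(method)
  validate_expression_matrix(mat, allow_duplicates = TRUE)
  ids <- rownames(mat)
  if (!anyDuplicated(ids)) return(mat)
  grp <- factor(ids, levels = unique(ids))
  if (method == "mean") {
    out <- rowsum(mat, grp, reorder = FALSE) / as.vector(table(grp))
  } else {
    out <- do.call(rbind, lapply(split(seq_along(ids), grp), function(ix) {
      apply(mat[ix, , drop = FALSE], 2L, max)
    }))
  }
  rownames(out) <- levels(grp)
  colnames(out) <- colnames(mat)
  out
}
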