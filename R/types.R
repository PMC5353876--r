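#' Construct an undirected interaction set
#'
#' Canonicalizes an edge list into a deduplicated, undirected interaction
#' set: self-loops are dropped, each edge is stored with its endpoints in
#' lexicographic order, and duplicate edges (in either orientation) are
#' merged. Edges are sorted so that the representation of a given edge set
#' is unique, which makes set operations and file output deterministic.
#'
#' Gene identifiers are opaque, case-sensitive strings; no symbol
#' normalization or aliasing is performed.
#'
#' @param from,to character vectors of equal length; the edge endpoints.
#' @param quiet suppress the message reporting dropped self-loops and
#'   merged duplicates.
#' @return An object of class `interaction_set`: a list with `edges`
#'   (a two-column character matrix in canonical order), and the counts
#'   `n_self_loops_dropped` and `n_duplicates_merged`.
#' @examples
#' es <- interaction_set(c("A", "B", "C", "A"), c("B", "A", "C", "B"))
#' n_edges(es)  # 1: B-A is A-B reversed, C-C is a self-loop
#' @export
interaction_set <- function(from, to, quiet = FALSE) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop("'from' and 'to' must have equal length")
  }
  self <- from == to
  n_self <- sum(self)
  from <- from[!self]
  to <- to[!self]
  u <- pmin(from, to)
  v <- pmax(from, to)
  key <- paste(u, v, sep = "\t")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  u <- u[!dup]
  v <- v[!dup]
  o <- order(u, v)
  edges <- cbind(u[o], v[o])
  colnames(edges) <- c("from", "to")
  if (!quiet && (n_self > 0L || n_dup > 0L)) {
    message(
      "interaction_set: dropped ", n_self, " self-loop(s), merged ",
      n_dup, " duplicate edge(s); ", nrow(edges), " edge(s) kept"
    )
  }
  structure(
    list(
      edges = edges,
      n_self_loops_dropped = n_self,
      n_duplicates_merged = n_dup
    ),
    class = "interaction_set"
  )
}

#' Number of edges in an interaction set or network
#' @param x an `interaction_set`, `stage_network` or `common_network`.
#' @return integer edge count.
#' @export
n_edges <- function(x) nrow(x$edges)

#' Nodes (endpoint union) of an interaction set or network
#' @param x an `interaction_set`, `stage_network` or `common_network`.
#' @return character vector of unique node identifiers, sorted.
#' @export
network_nodes <- function(x) sort(unique(as.vector(x$edges)))

# Canonical per-edge string keys, used for exact set operations.
edge_keys <- function(x) {
  e <- x$edges
  if (nrow(e) == 0L) character(0) else paste(e[, 1L], e[, 2L], sep = "\t")
}

# Inverse of edge_keys(); builds an interaction_set from canonical keys.
interaction_set_from_keys <- function(keys) {
  if (length(keys) == 0L) {
    return(interaction_set(character(0), character(0), quiet = TRUE))
  }
  parts <- strsplit(keys, "\t", fixed = TRUE)
  interaction_set(
    vapply(parts, `[[`, character(1), 1L),
    vapply(parts, `[[`, character(1), 2L),
    quiet = TRUE
  )
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(
    "Interaction set:", nrow(x$edges), "edges over",
    length(network_nodes(x)), "nodes\n"
  )
  invisible(x)
}

#' Construct a time-point grouping
#'
#' Maps ordered phenotype stages to the raw time-point columns they pool.
#' Adjacent time points sharing a phenotype are grouped into a stage and
#' their perturbation scores averaged downstream.
#'
#' @param stages a named list; each element is a character vector of raw
#'   time-point labels, in stage order. At least two stages, each
#'   non-empty, pairwise disjoint.
#' @return An object of class `time_grouping` (the validated named list).
#' @examples
#' time_grouping(list(early = c("t1", "t2"), late = c("t3", "t4")))
#' @export
time_grouping <- function(stages) {
  if (!is.list(stages) || is.null(names(stages)) ||
      any(!nzchar(names(stages)))) {
    stop("'stages' must be a named list of time-point label vectors")
  }
  if (anyDuplicated(names(stages))) {
    stop("duplicate stage labels: ",
         paste(unique(names(stages)[duplicated(names(stages))]),
               collapse = ", "))
  }
  stages <- lapply(stages, as.character)
  if (length(stages) < 2L) {
    stop("a time grouping needs at least 2 stages")
  }
  if (any(lengths(stages) == 0L)) {
    stop("every stage must contain at least one time-point label")
  }
  all_labels <- unlist(stages, use.names = FALSE)
  if (anyDuplicated(all_labels)) {
    stop("stages must be disjoint; repeated label(s): ",
         paste(unique(all_labels[duplicated(all_labels)]), collapse = ", "))
  }
  structure(stages, class = "time_grouping")
}

# Check a grouping against the column labels of an expression or score
# matrix; errors naming any label the matrix does not carry.
validate_grouping <- function(grouping, time_labels) {
  missing <- setdiff(unlist(grouping, use.names = FALSE), time_labels)
  if (length(missing) > 0L) {
    stop("grouping references absent column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.time_grouping <- function(x, ...) {
  cat("Time grouping with", length(x), "stages:\n")
  for (s in names(x)) {
    cat("  ", s, ": ", paste(x[[s]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Validate a gene x time-point expression matrix: numeric, finite, named,
# >= 2 time points. Duplicate gene ids are tolerated only when the caller
# intends to collapse them (allow_duplicates = TRUE).
validate_expression_matrix <- function(mat, allow_duplicates = FALSE) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("expression data must be a numeric matrix")
  }
  if (nrow(mat) < 1L) stop("expression matrix has no gene rows")
  if (ncol(mat) < 2L) stop("expression matrix needs at least 2 time points")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix must carry gene ids (rownames) and time labels (colnames)")
  }
  if (!allow_duplicates && anyDuplicated(rownames(mat))) {
    offender <- rownames(mat)[duplicated(rownames(mat))][1L]
    stop("duplicate gene id '", offender,
         "'; collapse duplicates first (see collapse_duplicate_genes)")
  }
  if (anyDuplicated(colnames(mat))) stop("duplicate time-point labels")
  if (!all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at gene '", rownames(mat)[bad[1L]],
         "', column '", colnames(mat)[bad[2L]], "'")
  }
  invisible(TRUE)
}
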