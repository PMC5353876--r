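#' Build a stage-specific network
#'
#' Keeps every scaffold interaction with at least one endpoint in the
#' stage's perturbed gene set. Endpoints never individually selected may
#' thus still appear as passive partners of a perturbed gene.
#'
#' @param perturbed character vector of perturbed gene ids for the stage.
#' @param scaffold an [interaction_set()] (the PPI scaffold).
#' @param stage_label label for the stage.
#' @return a `stage_network`: list with `stage`, `edges` (canonical
#'   two-column matrix, a subset of the scaffold).
#' @export
build_stage_network <- function(perturbed, scaffold, stage_label) {
  stopifnot(inherits(scaffold, "interaction_set"))
  perturbed <- as.character(perturbed)
  if (length(perturbed) == 0L) {
    warning("stage '", stage_label, "': empty perturbed gene set; ",
            "the stage network is empty")
  }
  e <- scaffold$edges
  keep <- e[, 1L] %in% perturbed | e[, 2L] %in% perturbed
  structure(
    list(stage = stage_label, edges = e[keep, , drop = FALSE]),
    class = "stage_network"
  )
}

#' Build all stage networks from selected gene sets
#'
#' @param selected a `perturbed_gene_sets` from [select_perturbed()].
#' @param scaffold an [interaction_set()].
#' @return named list of `stage_network`s, in stage order.
#' @export
stage_networks <- function(selected, scaffold) {
  stopifnot(inherits(selected, "perturbed_gene_sets"))
  nets <- lapply(names(selected$sets), function(st) {
    build_stage_network(selected$sets[[st]], scaffold, st)
  })
  names(nets) <- names(selected$sets)
  nets
}

#' @export
print.stage_network <- function(x, ...) {
  cat("Stage network '", x$stage, "': ", nrow(x$edges), " edges, ",
      length(unique(as.vector(x$edges))), " nodes\n", sep = "")
  invisible(x)
}

#' Extract the common (all-stage-conserved) network
#'
#' The common network is the exact set intersection of the stage-specific
#' edge sets: the interactions present at every stage. Its topology is
#' constant across stages while the node-level perturbation context may
#' shift, which is the structure the downstream delta-P test probes.
#'
#' @param networks list of >= 2 `stage_network`s.
#' @return a `common_network`: list with `edges`, `nodes` (endpoint union
#'   of the conserved edges) and `n_stages`. An empty intersection is
#'   allowed (zero-row `edges`).
#' @export
common_network <- function(networks) {
  if (length(networks) < 2L) stop("need at least 2 stage networks")
  if (!all(vapply(networks, inherits, logical(1), "stage_network"))) {
    stop("'networks' must be a list of stage_network objects")
  }
  keys <- lapply(networks, edge_keys)
  common_keys <- Reduce(intersect, keys)
  e1 <- networks[[1L]]$edges
  keep <- edge_keys(networks[[1L]]) %in% common_keys
  edges <- e1[keep, , drop = FALSE]
  structure(
    list(
      edges = edges,
      nodes = sort(unique(as.vector(edges))),
      n_stages = length(networks)
    ),
    class = "common_network"
  )
}

#' @export
print.common_network <- function(x, ...) {
  cat("Common network across", x$n_stages, "stages:", nrow(x$edges),
      "edges,", length(x$nodes), "nodes\n")
  invisible(x)
}

#' Average perturbation-score difference between two stages (delta-P)
#'
#' Over the member genes of the common network (all its nodes, including
#' passive endpoints), delta-P is the mean absolute difference between
#' their grouped, pre-threshold perturbation scores at two stages. It is
#' symmetric in the stage pair and zero for identical stages; a large
#' value says the conserved module's context shifted between the stages.
#'
#' @param common a non-empty `common_network`.
#' @param pm the grouped `perturbation_matrix` (pre-threshold scores).
#' @param stage_a,stage_b stage labels present in `pm`.
#' @return a `delta_p_result`: list with `stage_a`, `stage_b`, `delta_p`,
#'   `n_members` (genes averaged over) and `n_skipped` (common-network
#'   nodes absent from `pm`).
#' @export
average_delta_p <- function(common, pm, stage_a, stage_b) {
  stopifnot(inherits(common, "common_network"),
            inherits(pm, "perturbation_matrix"))
  if (!pm$grouped) stop("'pm' must be the grouped perturbation matrix")
  if (nrow(common$edges) == 0L) {
    stop("empty common network: delta-P is undefined")
  }
  for (st in c(stage_a, stage_b)) {
    if (!st %in% colnames(pm$scores)) stop("unknown stage: ", st)
  }
  genes <- common$nodes
  present <- genes %in% rownames(pm$scores)
  n_skipped <- sum(!present)
  genes <- genes[present]
  if (length(genes) == 0L) {
    stop("no common-network member gene has perturbation scores")
  }
  dp <- mean(abs(pm$scores[genes, stage_a] - pm$scores[genes, stage_b]))
  structure(
    list(stage_a = stage_a, stage_b = stage_b, delta_p = dp,
         n_members = length(genes), n_skipped = n_skipped),
    class = "delta_p_result"
  )
}

#' @export
print.delta_p_result <- function(x, ...) {
  cat(sprintf("delta-P(%s, %s) = %.6g over %d member gene(s)",
              x$stage_a, x$stage_b, x$delta_p, x$n_members))
  if (x$n_skipped > 0L) cat(" (", x$n_skipped, " node(s) skipped)", sep = "")
  cat("\n")
  invisible(x)
}

#' Restrict the analysis to a gene list
#'
#' For a focused analysis (e.g. known cell-cycle genes only), reduces the
#' scaffold to edges with BOTH endpoints in the list and the perturbation
#' matrix to the listed genes; the downstream pipeline is unchanged, so
#' the resulting common network contains only listed genes.
#'
#' @param scaffold an [interaction_set()].
#' @param pm a `perturbation_matrix` (grouped or not).
#' @param genes non-empty character vector of gene ids.
#' @return list with the reduced `scaffold` and `pm`.
#' @export
restrict_to_gene_list <- function(scaffold, pm, genes) {
  stopifnot(inherits(scaffold, "interaction_set"),
            inherits(pm, "perturbation_matrix"))
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene list is empty")
  keep_rows <- rownames(pm$scores) %in% genes
  if (!any(keep_rows)) {
    stop("no listed gene is present in the perturbation matrix")
  }
  e <- scaffold$edges
  keep <- e[, 1L] %in% genes & e[, 2L] %in% genes
  if (!any(keep)) {
    warning("no scaffold edge has both endpoints in the gene list; ",
            "the restricted scaffold is empty")
  }
  red_scaffold <- structure(
    list(edges = e[keep, , drop = FALSE],
         n_self_loops_dropped = 0L, n_duplicates_merged = 0L),
    class = "interaction_set"
  )
  red_pm <- structure(
    list(scores = pm$scores[keep_rows, , drop = FALSE], grouped = pm$grouped),
    class = "perturbation_matrix"
  )
  list(scaffold = red_scaffold, pm = red_pm)
}
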