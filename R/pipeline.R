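# Run one pipeline step, prefixing any error with the stage name so a
# failed run names where it failed.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the end-to-end conserved-module workflow
#'
#' Normalize (optional) -> perturbation scores -> optional gene-list
#' restriction -> stage grouping -> pooled mean +/- k sd threshold ->
#' per-stage perturbed sets and networks -> common network -> delta-P and
#' its resampling significance test for every adjacent stage pair plus
#' the (first, last) pair.
#'
#' @param expression path to an expression table, or a numeric matrix.
#' @param interactions path to an edge list, or an [interaction_set()].
#' @param grouping path to a grouping config, or a [time_grouping()].
#' @param gene_list optional path or character vector restricting the
#'   analysis to listed genes (both edge endpoints must be listed).
#' @param normalize quantile-normalize the expression matrix first
#'   (disable for pre-normalized inputs).
#' @param k threshold band half-width multiplier (see
#'   [compute_threshold()]).
#' @param threshold_on pool `"grouped"` (default) or `"ungrouped"` scores
#'   when estimating the threshold band.
#' @param n_iter resampling iterations per stage pair.
#' @param seed integer seed governing all randomness in the run.
#' @param null null model for [significance_test()].
#' @param dialect expression table dialect, when `expression` is a path.
#' @param output_dir optional directory; when given, score tables,
#'   per-stage networks, the common network (edge TSV and GraphML with
#'   per-stage node scores), a per-gene score-profile TSV and the
#'   key/value report are written there.
#' @return (invisibly) a `tscnet_pipeline` list: the intermediate objects
#'   (`pm`, `grouped`, `threshold`, `selected`, `networks`, `common`),
#'   per-pair `tests`, and `report` (the nested key/value summary,
#'   including per-stage node/edge counts and the percentage of scaffold
#'   interactions used).
#' @export
run_pipeline <- function(expression, interactions, grouping,
                         gene_list = NULL, normalize = TRUE, k = 1,
                         threshold_on = c("grouped", "ungrouped"),
                         n_iter = 10000, seed = NULL,
                         null = c("pooled", "label_permute"),
                         dialect = c("plain_tsv", "series_matrix"),
                         output_dir = NULL) {
  threshold_on <- match.arg(threshold_on)
  null <- match.arg(null)
  dialect <- match.arg(dialect)
  if (!is.null(seed)) set.seed(seed)

  expr <- with_stage("read_expression", {
    if (is.character(expression)) {
      read_expression_table(expression, dialect = dialect)
    } else {
      validate_expression_matrix(expression)
      expression
    }
  })
  scaffold <- with_stage("read_interactions", {
    if (is.character(interactions) && length(interactions) == 1L) {
      read_interactions(interactions, quiet = TRUE)
    } else {
      stopifnot(inherits(interactions, "interaction_set"))
      interactions
    }
  })
  tg <- with_stage("read_grouping", {
    if (is.character(grouping) && length(grouping) == 1L &&
        file.exists(grouping)) {
      read_grouping(grouping)
    } else if (inherits(grouping, "time_grouping")) {
      grouping
    } else {
      time_grouping(grouping)
    }
  })
  genes <- NULL
  if (!is.null(gene_list)) {
    genes <- with_stage("read_gene_list", {
      if (length(gene_list) == 1L && file.exists(gene_list)) {
        read_gene_list(gene_list)
      } else {
        as.character(gene_list)
      }
    })
  }

  if (normalize) {
    expr <- with_stage("normalize", quantile_normalize(expr))
  }
  pm <- with_stage("score", perturbation_scores(expr))
  if (!is.null(genes)) {
    red <- with_stage("gene_list_restriction",
                      restrict_to_gene_list(scaffold, pm, genes))
    scaffold <- red$scaffold
    pm <- red$pm
  }
  grouped <- with_stage("group", group_scores(pm, tg))
  threshold <- with_stage("threshold", compute_threshold(
    if (threshold_on == "grouped") grouped else pm, k = k
  ))
  selected <- with_stage("select", select_perturbed(grouped, threshold))
  networks <- with_stage("stage_networks", stage_networks(selected, scaffold))
  common <- with_stage("common_network", common_network(networks))

  stage_labels <- names(tg)
  n_stages <- length(stage_labels)
  pairs <- lapply(seq_len(n_stages - 1L),
                  function(i) stage_labels[c(i, i + 1L)])
  first_last <- stage_labels[c(1L, n_stages)]
  if (!any(vapply(pairs, identical, logical(1), first_last))) {
    pairs <- c(pairs, list(first_last))
  }

  tests <- list()
  if (nrow(common$edges) > 0L) {
    for (pr in pairs) {
      key <- paste(pr, collapse = " vs ")
      tests[[key]] <- with_stage(
        paste0("significance(", key, ")"),
        significance_test(networks, grouped, pr, n_iter = n_iter, null = null)
      )
    }
  }

  n_scaffold <- n_edges(scaffold)
  per_stage <- lapply(stage_labels, function(st) {
    net <- networks[[st]]
    list(
      n_perturbed_genes = length(selected$sets[[st]]),
      n_nodes = length(unique(as.vector(net$edges))),
      n_edges = nrow(net$edges),
      ratio_used_interactions_pct =
        if (n_scaffold > 0L) 100 * nrow(net$edges) / n_scaffold else NA_real_
    )
  })
  names(per_stage) <- stage_labels

  report <- list(
    input = list(
      n_genes = nrow(pm$scores),
      n_timepoints = ncol(pm$scores),
      n_stages = n_stages,
      n_scaffold_edges = n_scaffold,
      normalized = normalize,
      gene_list_size = if (is.null(genes)) 0L else length(genes),
      seed = if (is.null(seed)) NA_integer_ else seed,
      null_model = null,
      n_iter = n_iter
    ),
    threshold = list(
      mu = threshold$mu, sigma = threshold$sigma, k = threshold$k,
      lower = threshold$lower, upper = threshold$upper,
      pooled_on = threshold_on
    ),
    stages = per_stage,
    common_network = list(
      n_nodes = length(common$nodes),
      n_edges = nrow(common$edges),
      ratio_used_interactions_pct =
        if (n_scaffold > 0L) 100 * nrow(common$edges) / n_scaffold
        else NA_real_,
      empty = nrow(common$edges) == 0L
    )
  )
  if (nrow(common$edges) == 0L) {
    report$common_network$note <-
      "empty common network: significance testing skipped"
  }
  report$tests <- lapply(tests, function(tt) {
    list(
      observed_delta_p = tt$observed, null_mean = tt$null_mean,
      null_sd = tt$null_sd, empirical_p = tt$empirical_p,
      parametric_p = tt$parametric_p, n_iter = tt$n_iter,
      n_empty_intersections = tt$n_empty, n_members = tt$n_members
    )
  })

  result <- structure(
    list(
      expression = expr, scaffold = scaffold, grouping = tg,
      pm = pm, grouped = grouped, threshold = threshold,
      selected = selected, networks = networks, common = common,
      tests = tests, pairs = pairs, report = report
    ),
    class = "tscnet_pipeline"
  )

  if (!is.null(output_dir)) {
    with_stage("write_outputs", write_pipeline_outputs(result, output_dir))
  }
  invisible(result)
}

# Write every artifact of a pipeline run into a directory.
write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(output_dir, ...)
  write_expression_table(result$grouped$scores, p("scores_grouped.tsv"))
  write_expression_table(result$selected$final_scores, p("scores_final.tsv"))
  for (st in names(result$networks)) {
    write_network(result$networks[[st]],
                  p(paste0("network_", st, ".tsv")), "edge_tsv")
  }
  write_network(result$common, p("network_common.tsv"), "edge_tsv")
  if (nrow(result$common$edges) > 0L) {
    write_network(result$common, p("network_common.graphml"), "graphml",
                  scores = result$grouped)
    # score trajectories of the conserved module, one row per member gene
    members <- result$common$nodes
    members <- members[members %in% rownames(result$grouped$scores)]
    write_expression_table(
      result$grouped$scores[members, , drop = FALSE],
      p("common_score_profiles.tsv")
    )
  }
  write_report(result$report, p("report.txt"))
  invisible(output_dir)
}

#' @export
print.tscnet_pipeline <- function(x, ...) {
  r <- x$report
  cat("Conserved-module pipeline run\n")
  cat("  genes:", r$input$n_genes, " scaffold edges:",
      r$input$n_scaffold_edges, " stages:", r$input$n_stages, "\n")
  cat(sprintf("  threshold band: (%.4g, %.4g)  [k = %g]\n",
              r$threshold$lower, r$threshold$upper, r$threshold$k))
  for (st in names(r$stages)) {
    s <- r$stages[[st]]
    cat(sprintf("  %s: %d perturbed genes, %d nodes / %d edges (%.3f%%)\n",
                st, s$n_perturbed_genes, s$n_nodes, s$n_edges,
                s$ratio_used_interactions_pct))
  }
  cat(sprintf("  common network: %d nodes / %d edges (%.3f%%)\n",
              r$common_network$n_nodes, r$common_network$n_edges,
              r$common_network$ratio_used_interactions_pct))
  for (key in names(x$tests)) {
    tt <- x$tests[[key]]
    cat(sprintf(
      "  %s: delta-P %.4g, null %.4g +/- %.4g, empirical p %.4g, normal p %s\n",
      key, tt$observed, tt$null_mean, tt$null_sd, tt$empirical_p,
      if (is.na(tt$parametric_p)) "NA" else sprintf("%.4g", tt$parametric_p)
    ))
  }
  invisible(x)
}
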