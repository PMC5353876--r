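#' Pool the observed stage-network edges
#'
#' The resampling null draws from the set union of every stage network's
#' edges (an edge present at several stages contributes once).
#'
#' @param networks list of >= 2 `stage_network`s.
#' @return an [interaction_set()], the pooled edge collection.
#' @export
pooled_edges <- function(networks) {
  if (length(networks) < 2L) stop("need at least 2 stage networks")
  keys <- unique(unlist(lapply(networks, edge_keys), use.names = FALSE))
  if (length(keys) == 0L) stop("pooled edge collection is empty")
  interaction_set_from_keys(keys)
}

#' Draw random stage networks from the pooled edges
#'
#' For each stage, draws uniformly without replacement exactly as many
#' edges from the pool as the observed stage network contains; draws are
#' independent across stages. This is one resampling step of the null
#' model.
#'
#' @param pool an [interaction_set()] (see [pooled_edges()]).
#' @param sizes named integer vector of per-stage edge counts.
#' @return named list of `stage_network`s.
#' @export
sample_random_stage_networks <- function(pool, sizes) {
  stopifnot(inherits(pool, "interaction_set"))
  n_pool <- nrow(pool$edges)
  if (any(sizes > n_pool)) {
    stop("requested stage size exceeds pool size (", n_pool, " edges)")
  }
  labels <- names(sizes)
  if (is.null(labels)) labels <- paste0("stage", seq_along(sizes))
  nets <- lapply(seq_along(sizes), function(i) {
    idx <- sample.int(n_pool, sizes[[i]])
    structure(
      list(stage = labels[[i]], edges = pool$edges[idx, , drop = FALSE]),
      class = "stage_network"
    )
  })
  names(nets) <- labels
  nets
}

#' Resampling significance test for the delta-P statistic
#'
#' Tests the null hypothesis that the average difference of perturbation
#' scores between two stages is the same for the observed common network
#' and for a random one. Each iteration of the default `"pooled"` null
#' draws, per stage, a random edge set of the observed size from the
#' pooled observed edges, intersects the draws into a random common
#' network, and records its delta-P between the stage pair (0 when the
#' random intersection is empty; the empty count is reported rather than
#' discarded, since discarding would bias the null upward).
#'
#' The alternative `"label_permute"` null keeps the observed common
#' network and permutes the stage labels of the score columns before
#' computing delta-P; its support is limited by the number of stage
#' permutations and it is provided for sensitivity analysis only.
#'
#' Two p-values are reported: the empirical one,
#' `(1 + #(null >= observed)) / (n_iter + 1)` (never zero), and a
#' normal-approximation one, the upper tail of the observed delta-P under
#' `N(null mean, null sd)` — the convention that produces p-values far
#' below the 1/n_iter resolution of the empirical count.
#'
#' @param networks named list of observed `stage_network`s (>= 2).
#' @param pm the grouped `perturbation_matrix`.
#' @param stage_pair character vector of two stage labels.
#' @param n_iter number of resampling iterations (default 10000).
#' @param seed optional integer seed; recorded in the result.
#' @param null `"pooled"` (default) or `"label_permute"`.
#' @return a `significance_test` result: list with `stage_a`, `stage_b`,
#'   `observed`, `n_members`, `null_mean`, `null_sd`, `empirical_p`,
#'   `parametric_p` (`NA` when the null sd is zero), `n_iter`, `n_empty`
#'   (iterations with an empty random common network), `null_model`,
#'   `seed` and the raw `null_values`.
#' @export
significance_test <- function(networks, pm, stage_pair, n_iter = 10000,
                              seed = NULL,
                              null = c("pooled", "label_permute")) {
  null <- match.arg(null)
  stopifnot(inherits(pm, "perturbation_matrix"))
  if (!pm$grouped) stop("'pm' must be the grouped perturbation matrix")
  if (length(stage_pair) != 2L) stop("'stage_pair' must name two stages")
  if (!is.numeric(n_iter) || n_iter < 1) stop("'n_iter' must be >= 1")
  n_iter <- as.integer(n_iter)
  a <- stage_pair[[1L]]
  b <- stage_pair[[2L]]

  observed_common <- common_network(networks)
  if (nrow(observed_common$edges) == 0L) {
    stop("observed common network is empty; the observed delta-P is undefined")
  }
  obs <- average_delta_p(observed_common, pm, a, b)

  if (!is.null(seed)) set.seed(seed)
  null_values <- numeric(n_iter)
  n_empty <- 0L

  if (null == "pooled") {
    pool <- pooled_edges(networks)
    n_pool <- nrow(pool$edges)
    sizes <- vapply(networks, n_edges, integer(1))
    n_stage <- length(networks)
    # integer-indexed precomputation: per pool node, |score_a - score_b|
    nodes <- unique(as.vector(pool$edges))
    iu <- match(pool$edges[, 1L], nodes)
    iv <- match(pool$edges[, 2L], nodes)
    ridx <- match(nodes, rownames(pm$scores))
    d <- abs(pm$scores[ridx, a] - pm$scores[ridx, b])  # NA for absent genes
    for (it in seq_len(n_iter)) {
      drawn <- unlist(
        lapply(sizes, function(s) sample.int(n_pool, s)),
        use.names = FALSE
      )
      common_idx <- which(tabulate(drawn, n_pool) == n_stage)
      if (length(common_idx) == 0L) {
        n_empty <- n_empty + 1L
        next
      }
      dv <- d[unique(c(iu[common_idx], iv[common_idx]))]
      dv <- dv[!is.na(dv)]
      if (length(dv) == 0L) {
        n_empty <- n_empty + 1L
        next
      }
      null_values[it] <- mean(dv)
    }
  } else {
    stages <- colnames(pm$scores)
    pos <- match(c(a, b), stages)
    genes <- observed_common$nodes
    genes <- genes[genes %in% rownames(pm$scores)]
    s <- pm$scores[genes, , drop = FALSE]
    for (it in seq_len(n_iter)) {
      perm <- sample(length(stages))
      pa <- stages[perm[pos[1L]]]
      pb <- stages[perm[pos[2L]]]
      null_values[it] <- if (pa == pb) 0 else mean(abs(s[, pa] - s[, pb]))
    }
  }

  null_mean <- mean(null_values)
  null_sd <- stats::sd(null_values)
  empirical_p <- (1 + sum(null_values >= obs$delta_p)) / (n_iter + 1)
  parametric_p <- if (is.na(null_sd) || null_sd == 0) {
    NA_real_
  } else {
    stats::pnorm(obs$delta_p, mean = null_mean, sd = null_sd,
                 lower.tail = FALSE)
  }
  structure(
    list(
      stage_a = a, stage_b = b,
      observed = obs$delta_p, n_members = obs$n_members,
      null_mean = null_mean, null_sd = null_sd,
      empirical_p = empirical_p, parametric_p = parametric_p,
      n_iter = n_iter, n_empty = n_empty,
      null_model = null, seed = seed,
      null_values = null_values
    ),
    class = "significance_test"
  )
}

#' @export
print.significance_test <- function(x, ...) {
  cat(sprintf(
    paste0(
      "delta-P test (%s vs %s, %s null)\n",
      "  observed delta-P: %.4g (over %d member genes)\n",
      "  null: mean %.4g, sd %.4g (N = %d, %d empty intersections)\n",
      "  empirical p: %.4g   normal-approximation p: %s\n"
    ),
    x$stage_a, x$stage_b, x$null_model, x$observed, x$n_members,
    x$null_mean, x$null_sd, x$n_iter, x$n_empty, x$empirical_p,
    if (is.na(x$parametric_p)) "undefined (null sd = 0)"
    else sprintf("%.4g", x$parametric_p)
  ))
  invisible(x)
}
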