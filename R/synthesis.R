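#' Simulate an expression matrix and PPI scaffold with a planted module
#'
#' Generates the full input world for the pipeline: background genes are a
#' per-gene baseline (drawn from one common distribution, so quantile
#' normalization is near-neutral) plus i.i.d. Gaussian noise per time
#' point; planted module genes additionally drift linearly from
#' `-amplitude` to `+amplitude` across time points (a fraction
#' `direction_split` drifts upward, the rest mirror it downward — the two
#' opposed monotone profiles characteristic of a conserved module whose
#' context flips between the first and last phenotype). The scaffold is
#' `module_edges` random edges among the module genes plus
#' `scaffold_edges` random background edges among all gene pairs,
#' deduplicated with no self-loops. Time points are split into
#' `n_stages` consecutive equal blocks for the returned grouping.
#'
#' Defaults describe a 500-gene, 8-time-point (4 stages x 2) experiment on
#' a log2 intensity scale: replicate noise sd 0.2 and a peak module drift
#' of 1 (a two-fold change), i.e. an amplitude/noise ratio of 5, with a
#' background scaffold of 1000 edges (mean degree 4, the density scale of
#' a high-confidence PPI subnetwork).
#'
#' @param n_genes,n_timepoints problem size.
#' @param n_stages number of consecutive equal stages (`n_timepoints`
#'   must be divisible by it).
#' @param module_size,module_edges planted module genes and edges.
#' @param amplitude peak absolute drift of module genes, expression units.
#' @param noise_sd per-time-point Gaussian noise sd.
#' @param scaffold_edges background edge count.
#' @param direction_split fraction of module genes drifting upward.
#' @param baseline_mean,baseline_sd the common per-gene baseline
#'   distribution.
#' @param seed optional integer seed (full dataset is reproducible).
#' @return list with `expression` (matrix), `interactions`
#'   ([interaction_set()]), `grouping` ([time_grouping()]), the ground
#'   truth `module_genes` and `module_edges` (an [interaction_set()]),
#'   and `config` (the arguments used).
#' @export
simulate_dataset <- function(n_genes = 500, n_timepoints = 8, n_stages = 4,
                             module_size = 10, module_edges = 12,
                             amplitude = 1, noise_sd = 0.2,
                             scaffold_edges = 1000, direction_split = 0.5,
                             baseline_mean = 8, baseline_sd = 1.5,
                             seed = NULL) {
  if (module_size > n_genes) stop("module_size exceeds n_genes")
  if (module_edges > module_size * (module_size - 1) / 2) {
    stop("module_edges exceeds the number of module gene pairs")
  }
  if (scaffold_edges > n_genes * (n_genes - 1) / 2) {
    stop("scaffold_edges exceeds the number of gene pairs")
  }
  if (amplitude < 0 || noise_sd < 0) {
    stop("'amplitude' and 'noise_sd' must be >= 0")
  }
  if (n_timepoints %% n_stages != 0) {
    stop("'n_timepoints' must be divisible by 'n_stages'")
  }
  if (n_timepoints < 2L || n_stages < 2L) {
    stop("need at least 2 time points and 2 stages")
  }
  if (!is.null(seed)) set.seed(seed)

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  time_labels <- paste0("t", seq_len(n_timepoints))

  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  expr <- baseline + matrix(stats::rnorm(n_genes * n_timepoints, 0, noise_sd),
                            n_genes, n_timepoints)
  module_genes <- sort(sample(gene_ids, module_size))
  n_up <- round(direction_split * module_size)
  direction <- c(rep(1, n_up), rep(-1, module_size - n_up))
  ramp <- seq(-amplitude, amplitude, length.out = n_timepoints)
  mi <- match(module_genes, gene_ids)
  expr[mi, ] <- expr[mi, ] + outer(direction, ramp)
  dimnames(expr) <- list(gene_ids, time_labels)

  # planted module edges: uniform among module gene pairs
  mpairs <- utils::combn(module_genes, 2L)
  pick <- sample.int(ncol(mpairs), module_edges)
  mod_from <- mpairs[1L, pick]
  mod_to <- mpairs[2L, pick]

  # background edges: uniform among all gene pairs, rejection-sampled
  bg_u <- integer(0)
  bg_v <- integer(0)
  want <- scaffold_edges
  while (length(bg_u) < want) {
    m <- max(100L, 2L * (want - length(bg_u)))
    i <- sample.int(n_genes, m, replace = TRUE)
    j <- sample.int(n_genes, m, replace = TRUE)
    ok <- i != j
    u <- c(bg_u, pmin(i[ok], j[ok]))
    v <- c(bg_v, pmax(i[ok], j[ok]))
    keep <- !duplicated(paste(u, v))
    bg_u <- u[keep]
    bg_v <- v[keep]
  }
  bg_from <- gene_ids[bg_u[seq_len(want)]]
  bg_to <- gene_ids[bg_v[seq_len(want)]]

  interactions <- interaction_set(c(mod_from, bg_from), c(mod_to, bg_to),
                                  quiet = TRUE)

  blocks <- split(time_labels,
                  rep(seq_len(n_stages), each = n_timepoints / n_stages))
  names(blocks) <- paste0("stage", seq_len(n_stages))
  grouping <- time_grouping(blocks)

  list(
    expression = expr,
    interactions = interactions,
    grouping = grouping,
    module_genes = module_genes,
    module_edges = interaction_set(mod_from, mod_to, quiet = TRUE),
    config = list(
      n_genes = n_genes, n_timepoints = n_timepoints, n_stages = n_stages,
      module_size = module_size, module_edges = module_edges,
      amplitude = amplitude, noise_sd = noise_sd,
      scaffold_edges = scaffold_edges, direction_split = direction_split,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd, seed = seed
    )
  )
}

#' Five-gene worked-example fixture
#'
#' A small, fully worked dataset whose intermediate quantities are known
#' by construction: gene 3 has expression 0.2 at t2 against a temporal
#' mean of 0.45 (perturbation score -0.25), scores -0.15/-0.25 at t1/t2
#' (grouped stage score -0.2), the published toy threshold band is
#' (-0.376, 0.376) so gene 3's final score is 0, and genes 2 and 4 — the
#' two members of the toy common network — have grouped scores 0.5/-0.775
#' at the first stage and -0.45/0.475 at the last, giving delta-P
#' (|0.5-(-0.45)| + |-0.775-0.475|)/2 = 1.1.
#'
#' The threshold band is a stated constant of the example, not derived
#' from these five genes.
#'
#' @return list with `expression` (5 genes x 4 time points), `grouping`
#'   (stages `t1-2`, `t3`, `t4`), `scaffold` (3 edges, among them
#'   gene2-gene4), `threshold` (a `threshold_spec` with band +/- 0.376),
#'   `members` (genes 2 and 4) and `expected` (the quantities above).
#' @export
figure2_fixture <- function() {
  # per-gene perturbation rows (each sums to zero) + per-gene baselines
  p <- rbind(
    gene1 = c(0.10, 0.05, -0.05, -0.10),
    gene2 = c(0.50, 0.50, -0.55, -0.45),
    gene3 = c(-0.15, -0.25, 0.15, 0.25),
    gene4 = c(-0.775, -0.775, 1.075, 0.475),
    gene5 = c(0.20, -0.10, 0.00, -0.10)
  )
  baseline <- c(gene1 = 0.50, gene2 = 0.60, gene3 = 0.45,
                gene4 = 0.55, gene5 = 0.50)
  expression <- p + baseline
  colnames(expression) <- paste0("t", 1:4)
  grouping <- time_grouping(list(
    `t1-2` = c("t1", "t2"), t3 = "t3", t4 = "t4"
  ))
  scaffold <- interaction_set(
    c("gene2", "gene1", "gene3"),
    c("gene4", "gene3", "gene5"),
    quiet = TRUE
  )
  threshold <- structure(
    list(mu = 0, sigma = 0.376, k = 1, lower = -0.376, upper = 0.376),
    class = "threshold_spec"
  )
  list(
    expression = expression,
    grouping = grouping,
    scaffold = scaffold,
    threshold = threshold,
    members = c("gene2", "gene4"),
    expected = list(
      score_gene3_t2 = -0.25,
      grouped_gene3_stage1 = -0.2,
      final_gene3_stage1 = 0,
      delta_p_members = 1.1,
      delta_p_stages = c("t1-2", "t4")
    )
  )
}
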