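#' Per-gene, per-time-point perturbation scores
#'
#' The perturbation score of gene i at time point j is its expression
#' value minus the gene's mean expression over all M time points:
#' `p_ij = e_ij - (1/M) * sum_k e_ik`. Larger magnitudes mean the gene is
#' relatively perturbed at that time point; by construction each gene's
#' scores sum to zero across time points.
#'
#' @param mat numeric gene x time-point expression matrix (>= 2 columns).
#' @return an ungrouped `perturbation_matrix`: a list with `scores` (the
#'   gene x time-point score matrix) and `grouped = FALSE`.
#' @examples
#' m <- matrix(c(0.3, 0.2, 0.6, 0.7), 1, dimnames = list("g3", paste0("t", 1:4)))
#' perturbation_scores(m)$scores  # t2: 0.2 - 0.45 = -0.25
#' @export
perturbation_scores <- function(mat) {
  validate_expression_matrix(mat)
  if (ncol(mat) < 2L) {
    stop("perturbation scores need at least 2 time points; with one, ",
         "every mean-centered score is identically zero")
  }
  scores <- mat - rowMeans(mat)
  structure(list(scores = scores, grouped = FALSE),
            class = "perturbation_matrix")
}

#' Average perturbation scores over grouped time points
#'
#' When adjacent time points share a phenotype they are pooled into a
#' stage; the stage score of a gene is the arithmetic mean of its raw
#' per-time-point scores over that stage. Because scoring is linear this
#' equals centering the stage-averaged expression.
#'
#' @param pm an ungrouped `perturbation_matrix`.
#' @param grouping a [time_grouping()] over `pm`'s time labels.
#' @return a grouped `perturbation_matrix` (gene x stage).
#' @export
group_scores <- function(pm, grouping) {
  stopifnot(inherits(pm, "perturbation_matrix"))
  if (pm$grouped) stop("'pm' is already grouped")
  if (!inherits(grouping, "time_grouping")) grouping <- time_grouping(grouping)
  validate_grouping(grouping, colnames(pm$scores))
  g <- vapply(
    grouping,
    function(labs) rowMeans(pm$scores[, labs, drop = FALSE]),
    numeric(nrow(pm$scores))
  )
  if (nrow(pm$scores) == 1L) g <- matrix(g, nrow = 1L)
  dimnames(g) <- list(rownames(pm$scores), names(grouping))
  structure(list(scores = g, grouped = TRUE), class = "perturbation_matrix")
}

#' @export
print.perturbation_matrix <- function(x, ...) {
  cat(
    "Perturbation matrix:", nrow(x$scores), "genes x", ncol(x$scores),
    if (x$grouped) "stages (grouped)\n" else "time points (ungrouped)\n"
  )
  invisible(x)
}

#' Data-derived perturbation threshold
#'
#' Pools every entry of the score matrix (all genes x all stages), takes
#' mean `mu` and sample standard deviation `sigma`, and sets the selection
#' band to `mu +/- k * sigma`. Treating the pooled scores as approximately
#' normal, scores outside the band are called significantly perturbed.
#' `k = 1` is the default; larger k selects fewer genes (k = 2 or 3
#' typically leaves too few genes to build networks).
#'
#' @param pm a `perturbation_matrix`; normally the grouped one, so the
#'   thresholds apply to the same values they are compared against
#'   (pooling ungrouped scores instead is possible by passing them here).
#' @param k positive band half-width multiplier.
#' @return a `threshold_spec`: list with `mu`, `sigma`, `k`, `lower`,
#'   `upper`.
#' @export
compute_threshold <- function(pm, k = 1) {
  stopifnot(inherits(pm, "perturbation_matrix"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("'k' must be a single positive number")
  }
  x <- as.vector(pm$scores)
  if (length(x) < 2L) stop("need at least 2 scores to estimate a threshold")
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (sigma == 0) {
    stop("all perturbation scores are equal (sigma = 0); ",
         "supply a manual threshold instead")
  }
  structure(
    list(mu = mu, sigma = sigma, k = k,
         lower = mu - k * sigma, upper = mu + k * sigma),
    class = "threshold_spec"
  )
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf(
    "Threshold: mu = %.6g, sigma = %.6g, k = %g, band (%.6g, %.6g)\n",
    x$mu, x$sigma, x$k, x$lower, x$upper
  ))
  invisible(x)
}

#' Select perturbed genes per stage
#'
#' A gene's final score at a stage is its grouped score when that score
#' lies strictly outside the threshold band (`> upper` or `< lower`) and
#' zero otherwise; a gene joins a stage's perturbed set exactly when its
#' final score is nonzero. Boundary values are excluded (strict
#' inequalities).
#'
#' @param pm a grouped `perturbation_matrix`.
#' @param spec a `threshold_spec` from [compute_threshold()], or any list
#'   with `lower` and `upper`.
#' @return a `perturbed_gene_sets`: list with `sets` (per-stage character
#'   vectors), `final_scores` (gene x stage matrix, zero inside the band)
#'   and the `threshold` used.
#' @export
select_perturbed <- function(pm, spec) {
  stopifnot(inherits(pm, "perturbation_matrix"))
  if (!pm$grouped) {
    stop("'pm' must be grouped (stage scores) before thresholding")
  }
  if (is.null(spec$lower) || is.null(spec$upper) || spec$lower >= spec$upper) {
    stop("'spec' must provide lower < upper")
  }
  s <- pm$scores
  outside <- s > spec$upper | s < spec$lower
  final <- ifelse(outside, s, 0)
  sets <- lapply(colnames(s), function(st) rownames(s)[final[, st] != 0])
  names(sets) <- colnames(s)
  structure(
    list(sets = sets, final_scores = final, threshold = spec),
    class = "perturbed_gene_sets"
  )
}

#' @export
print.perturbed_gene_sets <- function(x, ...) {
  cat("Perturbed gene sets per stage:\n")
  for (st in names(x$sets)) {
    cat("  ", st, ": ", length(x$sets[[st]]), " gene(s)\n", sep = "")
  }
  invisible(x)
}
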