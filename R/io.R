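#' Read a gene x time-point expression table
#'
#' Parses a tab-separated expression table with a header row of time-point
#' labels and one gene identifier per row. Two dialects are supported:
#' `plain_tsv` skips lines starting with `#`; `series_matrix` handles the
#' GEO series-matrix convention, ignoring `!`-prefixed metadata lines and,
#' when present, parsing only the block between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers
#' (quoted fields are unquoted).
#'
#' @param path path to the table.
#' @param dialect `"plain_tsv"` (default) or `"series_matrix"`.
#' @param allow_duplicates keep duplicate gene ids (e.g. multiple probes
#'   per gene) for later collapsing with [collapse_duplicate_genes()];
#'   by default a duplicate id is an error naming the offender.
#' @return a numeric matrix, genes x time points, with gene ids as
#'   rownames and time labels as colnames. No transformation is applied;
#'   values are taken as provided (intensity or log scale).
#' @export
read_expression_table <- function(path,
                                  dialect = c("plain_tsv", "series_matrix"),
                                  allow_duplicates = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (length(begin) >= 1L && length(end) >= 1L && end[1L] > begin[1L]) {
      lines <- lines[(begin[1L] + 1L):(end[1L] - 1L)]
    } else {
      lines <- lines[!startsWith(lines, "!")]
    }
    lines <- gsub('"', "", lines, fixed = TRUE)
  } else {
    lines <- lines[!startsWith(lines, "#")]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("expression table needs a header line and at least one gene row")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  time_labels <- header[-1L]
  if (length(time_labels) < 2L) {
    stop("expression table needs at least 2 time-point columns, found ",
         length(time_labels))
  }
  body <- fields[-1L]
  nf <- lengths(body)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1L]
    stop("line ", bad + 1L, ": expected ", length(header),
         " tab-separated fields, found ", nf[bad])
  }
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  values <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(length(time_labels)))
  )
  values <- t(matrix(values, nrow = length(time_labels)))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("non-numeric expression value for gene '", gene_ids[bad[1L]],
         "' in column '", time_labels[bad[2L]], "'")
  }
  dimnames(values) <- list(gene_ids, time_labels)
  validate_expression_matrix(values, allow_duplicates = allow_duplicates)
  values
}

#' Write an expression (or score) matrix as TSV
#'
#' First column `gene`, then one column per time point or stage;
#' [read_expression_table()] on the output reproduces the matrix.
#'
#' @param mat numeric matrix with gene rownames and column labels.
#' @param path output path.
#' @export
write_expression_table <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an undirected interaction (edge) list
#'
#' Each non-comment line carries two tab-separated gene symbols (extra
#' fields are ignored). Self-loops are dropped and duplicate edges under
#' endpoint reordering merged, with counts reported via `message()`.
#'
#' @param path path to the edge list; `#`-prefixed lines are comments.
#' @param quiet suppress the dedup message.
#' @return an [interaction_set()].
#' @export
read_interactions <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  kept_idx <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty interaction file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop("line ", kept_idx[bad], ": expected at least 2 tab-separated ",
         "fields, found ", nf[bad])
  }
  interaction_set(
    vapply(fields, `[[`, character(1), 1L),
    vapply(fields, `[[`, character(1), 2L),
    quiet = quiet
  )
}

#' Read a plain gene list (one identifier per line)
#'
#' `#`-prefixed lines and blank lines are skipped; duplicates are removed
#' preserving first occurrence.
#'
#' @param path path to the list.
#' @return character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty gene list: ", path)
  unique(lines)
}

#' Write a gene list, one identifier per line
#' @param genes character vector.
#' @param path output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a stage grouping configuration
#'
#' Two formats are accepted, detected from content: a JSON object mapping
#' stage label to an array of raw column labels (order-preserving), or a
#' two-column TSV of `stage<TAB>column` rows where stages appear in order
#' of first occurrence.
#'
#' @param path path to the config file.
#' @return a [time_grouping()].
#' @export
read_grouping <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) stop("empty grouping file: ", path)
  if (startsWith(trimws(nonblank[1L]), "{")) {
    stages <- jsonlite::fromJSON(paste(lines, collapse = "\n"),
                                 simplifyVector = TRUE)
    stages <- lapply(stages, as.character)
    return(time_grouping(stages))
  }
  keep <- nonblank[!startsWith(nonblank, "#")]
  fields <- strsplit(keep, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("grouping TSV needs 'stage<TAB>column' on every line")
  }
  stage <- vapply(fields, `[[`, character(1), 1L)
  column <- vapply(fields, `[[`, character(1), 2L)
  time_grouping(split(column, factor(stage, levels = unique(stage))))
}

#' Write a stage grouping configuration as JSON
#' @param grouping a [time_grouping()].
#' @param path output path.
#' @export
write_grouping <- function(grouping, path) {
  jsonlite::write_json(unclass(grouping), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' Write a network or interaction set to file
#'
#' `edge_tsv` writes a two-column tab-separated edge list (re-readable
#' with [read_interactions()]). `graphml` writes GraphML via igraph; when
#' a grouped perturbation matrix is supplied its per-stage scores are
#' attached as node attributes (`score.<stage>`), so downstream viewers
#' can color the conserved module by its shifting context.
#'
#' @param x an `interaction_set`, `stage_network` or `common_network`.
#' @param path output path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @param scores optional grouped `perturbation_matrix` supplying node
#'   attributes for GraphML output.
#' @export
write_network <- function(x, path, format = c("edge_tsv", "graphml"),
                          scores = NULL) {
  format <- match.arg(format)
  e <- x$edges
  if (format == "edge_tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# from\tto", con)
    if (nrow(e) > 0L) {
      writeLines(paste(e[, 1L], e[, 2L], sep = "\t"), con)
    }
    return(invisible(path))
  }
  nodes <- sort(unique(as.vector(e)))
  vdf <- data.frame(name = nodes, stringsAsFactors = FALSE)
  if (!is.null(scores)) {
    if (!inherits(scores, "perturbation_matrix")) {
      stop("'scores' must be a perturbation_matrix")
    }
    s <- scores$scores
    idx <- match(nodes, rownames(s))
    for (st in colnames(s)) {
      vdf[[paste0("score.", st)]] <- s[idx, st]
    }
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(e, stringsAsFactors = FALSE),
    directed = FALSE, vertices = vdf
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a network file written by [write_network()]
#' @param path input path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return an [interaction_set()].
#' @export
read_network <- function(path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    return(read_interactions(path, quiet = TRUE))
  }
  g <- igraph::read_graph(path, format = "graphml")
  e <- igraph::as_edgelist(g, names = TRUE)
  interaction_set(e[, 1L], e[, 2L], quiet = TRUE)
}

#' Write a structured key/value text report
#'
#' Flattens a (possibly nested) named list into `key<TAB>value` lines;
#' nested names are joined with `.`. Numeric values are written with full
#' precision so reports are reproducible records of a run.
#'
#' @param results named list.
#' @param path output path.
#' @export
write_report <- function(results, path) {
  flatten <- function(x, prefix = character(0)) {
    out <- character(0)
    for (nm in names(x)) {
      key <- paste(c(prefix, nm), collapse = ".")
      val <- x[[nm]]
      if (is.list(val)) {
        out <- c(out, flatten(val, c(prefix, nm)))
      } else {
        out <- c(out, paste0(
          key, "\t",
          paste(vapply(val, format, character(1), digits = 15),
                collapse = ",")
        ))
      }
    }
    out
  }
  writeLines(flatten(results), path)
  invisible(path)
}
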