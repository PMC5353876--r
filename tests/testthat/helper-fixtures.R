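# Shared generators and independent oracles for the test suite.

# random gene x time-point matrix with dimnames
random_expression <- function(n_genes, n_timepoints, sd = 1, mean = 8) {
  m <- matrix(rnorm(n_genes * n_timepoints, mean, sd), n_genes, n_timepoints)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      paste0("t", seq_len(n_timepoints)))
  m
}

# random edge list over a node alphabet, possibly with duplicates/loops
random_edges <- function(n_edges, nodes) {
  u <- sample(nodes, n_edges, replace = TRUE)
  v <- sample(nodes, n_edges, replace = TRUE)
  list(from = u, to = v)
}

random_interaction_set <- function(n_edges, nodes) {
  e <- random_edges(n_edges, nodes)
  suppressMessages(interaction_set(e$from, e$to))
}

edge_key_set <- function(x) {
  e <- x$edges
  if (nrow(e) == 0L) character(0) else paste(e[, 1L], e[, 2L], sep = "\t")
}

# brute-force common-network oracle: checks every scaffold edge for
# membership in every stage network, one edge at a time
oracle_common_edges <- function(scaffold, networks) {
  keys <- edge_key_set(scaffold)
  net_keys <- lapply(networks, edge_key_set)
  keep <- vapply(keys, function(k) {
    all(vapply(net_keys, function(nk) k %in% nk, logical(1)))
  }, logical(1))
  sort(keys[keep])
}

# write lines to a temp file, return path
tmpfile_with <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
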