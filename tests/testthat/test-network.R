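simple_scaffold <- function(pairs) {
  suppressMessages(interaction_set(
    vapply(pairs, `[[`, character(1), 1L),
    vapply(pairs, `[[`, character(1), 2L)
  ))
}

test_that("stage networks keep edges with at least one perturbed endpoint", {
  sc <- simple_scaffold(list(c("A", "B"), c("B", "C"), c("C", "D")))
  expect_identical(edge_key_set(build_stage_network("A", sc, "s")), "A\tB")
  expect_identical(edge_key_set(build_stage_network("B", sc, "s")),
                   c("A\tB", "B\tC"))
  # saturation: everything perturbed selects the whole scaffold
  expect_identical(edge_key_set(build_stage_network(LETTERS[1:4], sc, "s")),
                   edge_key_set(sc))
  # empty perturbed set: empty network with a warning, not an error
  expect_warning(net <- build_stage_network(character(0), sc, "s"),
                 "empty perturbed")
  expect_equal(nrow(net$edges), 0L)
})

test_that("common network is the exact all-stage edge intersection", {
  sc <- simple_scaffold(list(c("A", "B"), c("B", "C"), c("C", "D")))
  mk <- function(keys) {
    structure(list(stage = "x", edges = do.call(
      rbind, lapply(strsplit(keys, "\t"), identity)
    )), class = "stage_network")
  }
  cn <- common_network(list(mk(c("A\tB", "B\tC")), mk(c("A\tB", "C\tD")),
                            mk("A\tB")))
  expect_identical(edge_key_set(cn), "A\tB")
  expect_identical(cn$nodes, c("A", "B"))

  # idempotence on identical stages
  nets <- list(mk(c("A\tB", "B\tC")), mk(c("A\tB", "B\tC")))
  expect_identical(edge_key_set(common_network(nets)),
                   c("A\tB", "B\tC"))
  # disjoint stages: empty common network allowed
  cn0 <- common_network(list(mk("A\tB"), mk("C\tD")))
  expect_equal(nrow(cn0$edges), 0L)
  expect_error(common_network(list(mk("A\tB"))), "at least 2")
})

test_that("common network matches the brute-force oracle on random instances", {
  withr::local_seed(31)
  nodes <- sprintf("n%03d", 1:40)
  for (rep in 1:30) {
    sc <- random_interaction_set(sample(20:200, 1), nodes)
    n_stages <- sample(3:6, 1)
    nets <- lapply(seq_len(n_stages), function(i) {
      perturbed <- sample(nodes, sample(3:15, 1))
      build_stage_network(perturbed, sc, paste0("s", i))
    })
    cn <- common_network(nets)
    expect_identical(sort(edge_key_set(cn)), oracle_common_edges(sc, nets))
    # subset of every stage
    for (net in nets) {
      expect_true(all(edge_key_set(cn) %in% edge_key_set(net)))
    }
    # adding a stage never enlarges the intersection
    extra <- build_stage_network(sample(nodes, 5), sc, "extra")
    cn2 <- common_network(c(nets, list(extra)))
    expect_true(all(edge_key_set(cn2) %in% edge_key_set(cn)))
  }
})

test_that("delta-P reproduces the worked example and its symmetries", {
  fx <- figure2_fixture()
  g <- group_scores(perturbation_scores(fx$expression), fx$grouping)
  sel <- select_perturbed(g, fx$threshold)
  cn <- common_network(stage_networks(sel, fx$scaffold))
  expect_identical(sort(cn$nodes), c("gene2", "gene4"))

  dp <- average_delta_p(cn, g, "t1-2", "t4")
  expect_equal(dp$delta_p, 1.1)
  expect_equal(dp$n_members, 2L)
  # symmetry and self-comparison
  expect_equal(average_delta_p(cn, g, "t4", "t1-2")$delta_p, 1.1)
  expect_equal(average_delta_p(cn, g, "t3", "t3")$delta_p, 0)

  # genes absent from the score matrix are skipped and counted
  g_small <- structure(
    list(scores = g$scores["gene2", , drop = FALSE], grouped = TRUE),
    class = "perturbation_matrix"
  )
  dp2 <- average_delta_p(cn, g_small, "t1-2", "t4")
  expect_equal(dp2$n_skipped, 1L)
  expect_equal(dp2$delta_p, 0.95)

  empty <- structure(list(edges = matrix(character(0), 0, 2),
                          nodes = character(0), n_stages = 2L),
                     class = "common_network")
  expect_error(average_delta_p(empty, g, "t3", "t4"), "undefined")
  expect_error(average_delta_p(cn, g, "t1-2", "nope"), "unknown stage")
})

test_that("gene-list restriction induces the listed subgraph", {
  sc <- simple_scaffold(list(c("A", "B"), c("B", "C"), c("C", "D")))
  pm <- perturbation_scores(matrix(
    rnorm(8), 4, 2, dimnames = list(c("A", "B", "C", "D"), c("t1", "t2"))
  ))
  red <- restrict_to_gene_list(sc, pm, c("A", "B", "C"))
  expect_identical(edge_key_set(red$scaffold), c("A\tB", "B\tC"))
  expect_identical(rownames(red$pm$scores), c("A", "B", "C"))

  # full list: identity
  red_all <- restrict_to_gene_list(sc, pm, c("A", "B", "C", "D"))
  expect_identical(edge_key_set(red_all$scaffold), edge_key_set(sc))

  # list disjoint from scaffold nodes: empty scaffold with a warning
  pm_x <- perturbation_scores(matrix(
    rnorm(4), 2, 2, dimnames = list(c("X", "Y"), c("t1", "t2"))
  ))
  expect_warning(red0 <- restrict_to_gene_list(sc, pm_x, c("X", "Y")),
                 "empty")
  expect_equal(nrow(red0$scaffold$edges), 0L)
  # no listed gene scored at all: error
  expect_error(restrict_to_gene_list(sc, pm, c("X", "Y")),
               "no listed gene")
})
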