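test_that("perturbation scores are mean-centered deviations", {
  # worked example: expression 0.2 at t2 against a temporal mean of 0.45
  m <- matrix(c(0.3, 0.2, 0.6, 0.7), 1,
              dimnames = list("gene3", paste0("t", 1:4)))
  pm <- perturbation_scores(m)
  expect_false(pm$grouped)
  expect_equal(pm$scores["gene3", "t2"], -0.25)

  # constant row centers to zero
  const <- matrix(5, 1, 4, dimnames = list("g", paste0("t", 1:4)))
  expect_equal(unname(perturbation_scores(const)$scores), matrix(0, 1, 4))

  # every row of scores sums to zero
  withr::local_seed(21)
  x <- random_expression(50, 6)
  expect_true(all(abs(rowSums(perturbation_scores(x)$scores)) < 1e-9))

  # degenerate single-time-point input
  one <- matrix(1:3, 3, 1, dimnames = list(paste0("g", 1:3), "t1"))
  expect_error(perturbation_scores(one), "at least 2 time points")
})

test_that("grouping averages stage scores and commutes with scoring", {
  # worked example: scores -0.15 (t1) and -0.25 (t2) average to -0.2
  fx <- figure2_fixture()
  pm <- perturbation_scores(fx$expression)
  g <- group_scores(pm, fx$grouping)
  expect_true(g$grouped)
  expect_equal(pm$scores["gene3", "t1"], -0.15)
  expect_equal(g$scores["gene3", "t1-2"], -0.2)

  # singleton stages: identity grouping
  withr::local_seed(22)
  x <- random_expression(10, 4)
  pmx <- perturbation_scores(x)
  singleton <- time_grouping(as.list(setNames(colnames(x), colnames(x))))
  expect_equal(unname(group_scores(pmx, singleton)$scores),
               unname(pmx$scores))

  # linearity: averaging expression per stage then centering equals
  # centering then averaging the scores
  tg <- time_grouping(list(a = c("t1", "t2"), b = c("t3", "t4")))
  for (rep in 1:5) {
    x <- random_expression(20, 4)
    route1 <- group_scores(perturbation_scores(x), tg)$scores
    stage_means <- cbind(a = rowMeans(x[, 1:2]), b = rowMeans(x[, 3:4]))
    route2 <- stage_means - rowMeans(x)
    expect_equal(unname(route1), unname(route2), tolerance = 1e-12)
  }

  expect_error(group_scores(g, tg), "already grouped")
})

test_that("threshold pools all scores with sample sd", {
  # pooled scores {-1, 0, 1}: mu 0, sample sd 1, band (-1, 1)
  pm <- structure(
    list(scores = matrix(c(-1, 0, 1), 1,
                         dimnames = list("g", c("a", "b", "c"))),
         grouped = TRUE),
    class = "perturbation_matrix"
  )
  th <- compute_threshold(pm, k = 1)
  expect_equal(th$mu, 0)
  expect_equal(th$sigma, 1)
  expect_equal(c(th$lower, th$upper), c(-1, 1))

  # symmetric scores: band approximately +/- sd
  withr::local_seed(23)
  x <- random_expression(200, 4, mean = 0)
  g <- group_scores(perturbation_scores(x),
                    time_grouping(list(a = c("t1", "t2"),
                                       b = c("t3", "t4"))))
  th1 <- compute_threshold(g)
  expect_equal(th1$upper, -th1$lower + 2 * th1$mu)
  expect_equal(th1$sigma, sd(as.vector(g$scores)))

  # sigma = 0 asks for a manual threshold
  flat <- structure(
    list(scores = matrix(0.5, 2, 2,
                         dimnames = list(c("g1", "g2"), c("a", "b"))),
         grouped = TRUE),
    class = "perturbation_matrix"
  )
  expect_error(compute_threshold(flat), "manual threshold")
  expect_error(compute_threshold(pm, k = 0), "positive")
})

test_that("selection zeroes in-band scores with strict boundaries", {
  fx <- figure2_fixture()
  g <- group_scores(perturbation_scores(fx$expression), fx$grouping)
  sel <- select_perturbed(g, fx$threshold)
  # -0.2 lies inside (-0.376, 0.376): final score 0, gene excluded
  expect_equal(sel$final_scores["gene3", "t1-2"], 0)
  expect_false("gene3" %in% sel$sets[["t1-2"]])
  # 0.5 lies outside: kept verbatim, gene included
  expect_equal(sel$final_scores["gene2", "t1-2"], 0.5)
  expect_true("gene2" %in% sel$sets[["t1-2"]])

  # a score exactly on the boundary is excluded
  pm <- structure(
    list(scores = matrix(c(0.376, 0.3761), 1,
                         dimnames = list("g", c("a", "b"))),
         grouped = TRUE),
    class = "perturbation_matrix"
  )
  selb <- select_perturbed(pm, fx$threshold)
  expect_equal(unname(selb$final_scores[1, ]), c(0, 0.3761))

  # grouped input required
  expect_error(select_perturbed(perturbation_scores(fx$expression),
                                fx$threshold), "grouped")
})

test_that("selection is monotone in k and respects the closed band", {
  withr::local_seed(24)
  x <- random_expression(150, 6, mean = 0)
  tg <- time_grouping(list(a = c("t1", "t2"), b = c("t3", "t4"),
                           c = c("t5", "t6")))
  g <- group_scores(perturbation_scores(x), tg)
  ks <- c(0.5, 1, 1.5, 2)
  sets_by_k <- lapply(ks, function(k) {
    select_perturbed(g, compute_threshold(g, k = k))$sets
  })
  for (i in seq_along(ks)[-1]) {
    for (st in names(sets_by_k[[i]])) {
      expect_true(all(sets_by_k[[i]][[st]] %in% sets_by_k[[i - 1]][[st]]))
    }
  }
  # no selected gene's grouped score lies inside the closed band
  th <- compute_threshold(g, k = 1)
  sel <- select_perturbed(g, th)
  for (st in names(sel$sets)) {
    s <- g$scores[sel$sets[[st]], st]
    expect_true(all(s > th$upper | s < th$lower))
  }
})
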