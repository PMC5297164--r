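# Weak Pareto dominance and the three-way desirability classification.

test_that("dominates implements weak Pareto dominance", {
  expect_true(dominates(c(6, 4), c(5, 4)))    # better on one, equal other
  expect_true(dominates(c(5, 4), c(3, 4)))
  expect_true(dominates(c(2, 2), c(1, 1)))
  expect_false(dominates(c(8, 1), c(2, 8)))   # incomparable both ways
  expect_false(dominates(c(2, 8), c(8, 1)))
  expect_false(dominates(c(3, 3), c(3, 3)))   # exact ties never dominate
  # one-row data frame input
  a <- tibble::tibble(influence_rank = 5, difficulty_rank = 4)
  b <- tibble::tibble(influence_rank = 5, difficulty_rank = 1)
  expect_true(dominates(a, b))
  expect_false(dominates(b, a))
})

test_that("dominance is a strict partial order on random point sets", {
  set.seed(91)
  for (rep in 1:50) {
    pts <- random_points(sample(3:9, 1), max_rank = sample(3:6, 1))
    n <- nrow(pts)
    d <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      d[i, j] <- dominates(c(pts$influence_rank[i], pts$difficulty_rank[i]),
                           c(pts$influence_rank[j], pts$difficulty_rank[j]))
    }
    expect_false(any(diag(d)))                      # irreflexive
    expect_false(any(d & t(d)))                     # asymmetric
    # transitive: d2 <- d %*% d reachable in two steps implies direct edge
    d2 <- (d %*% d) > 0
    expect_true(all(d[d2]))
  }
})

test_that("classification reproduces the published worked examples", {
  # blood-glucose behaviour: one barrier dominates the other outright
  bgl <- tibble::tibble(barrier_id = c("6.2", "6.1"),
                        influence_rank = c(2, 1), difficulty_rank = c(2, 1))
  r <- classify_barriers(bgl, "6")
  expect_equal(as.character(r$labels$desirability), c("most_desirable",
                                                      "least_desirable"))

  # swallow-screen behaviour: four nondominated, four dominated, no overall best
  nbm <- tibble::tibble(
    barrier_id = c("8.2", "8.4", "8.5", "8.8", "8.1", "8.3", "8.6", "8.7"),
    influence_rank = c(8, 5, 6, 2, 5, 5, 3, 2),
    difficulty_rank = c(1, 6, 4, 8, 2, 4, 4, 7))
  r <- classify_barriers(nbm, "8")
  lab <- setNames(as.character(r$labels$desirability), r$labels$barrier_id)
  expect_equal(unname(lab[c("8.2", "8.4", "8.5", "8.8")]), rep("desirable", 4))
  expect_equal(unname(lab[c("8.1", "8.3", "8.6", "8.7")]),
               rep("least_desirable", 4))

  # transfer behaviour: a perfect anti-chain, everything desirable
  su <- tibble::tibble(barrier_id = paste0("9.", 1:4),
                       influence_rank = 4:1, difficulty_rank = 1:4)
  r <- classify_barriers(su, "9")
  expect_equal(as.character(r$labels$desirability), rep("desirable", 4))

  # temperature behaviour: 4.1 weakly dominates everything else
  temp <- tibble::tibble(
    barrier_id = paste0("4.", 1:5),
    influence_rank = c(5, 5, 3, 2, 3), difficulty_rank = c(4, 1, 2, 3, 4))
  r <- classify_barriers(temp, "4")
  lab <- setNames(as.character(r$labels$desirability), r$labels$barrier_id)
  expect_equal(unname(lab["4.1"]), "most_desirable")
  expect_equal(unname(lab[paste0("4.", 2:5)]), rep("least_desirable", 4))
})

test_that("a dominating pair is forced to {most, least}", {
  pts <- tibble::tibble(barrier_id = c("x", "y"),
                        influence_rank = c(2, 1), difficulty_rank = c(2, 2))
  r <- classify_barriers(pts)
  expect_equal(as.character(r$labels$desirability),
               c("most_desirable", "least_desirable"))
})

test_that("exact ties share a label, including most_desirable", {
  pts <- tibble::tibble(barrier_id = c("x", "y", "z"),
                        influence_rank = c(3, 3, 1),
                        difficulty_rank = c(3, 3, 1))
  r <- classify_barriers(pts)
  lab <- setNames(as.character(r$labels$desirability), r$labels$barrier_id)
  expect_equal(unname(lab[c("x", "y")]), rep("most_desirable", 2))
  expect_equal(unname(lab["z"]), "least_desirable")
})

test_that("classification equals the all-pairs oracle on random point sets", {
  set.seed(92)
  for (rep in 1:100) {
    pts <- random_points(sample(2:9, 1), max_rank = sample(2:9, 1))
    r <- classify_barriers(pts)
    expect_equal(as.character(r$labels$desirability), classify_oracle(pts))
  }
})

test_that("dominance edges identify every least-desirable barrier's dominator", {
  set.seed(93)
  for (rep in 1:30) {
    pts <- random_points(sample(3:8, 1))
    r <- classify_barriers(pts)
    lab <- as.character(r$labels$desirability)
    dominated_ids <- unique(r$dominance_edges$dominated)
    expect_setequal(r$labels$barrier_id[lab == "least_desirable"], dominated_ids)
  }
})

test_that("labels are invariant under strictly increasing axis transforms", {
  set.seed(94)
  for (rep in 1:20) {
    pts <- random_points(sample(3:8, 1))
    r0 <- classify_barriers(pts)
    pts2 <- pts
    pts2$influence_rank <- pts$influence_rank^2
    pts2$difficulty_rank <- 3 * pts$difficulty_rank + 1
    r2 <- classify_barriers(pts2)
    expect_equal(r0$labels$desirability, r2$labels$desirability)
  }
})

test_that("classify rejects degenerate inputs", {
  pts <- tibble::tibble(barrier_id = c("a", "a"),
                        influence_rank = 1:2, difficulty_rank = 1:2)
  expect_error(classify_barriers(pts), "duplicate")
  expect_error(classify_barriers(pts[1, ]), "at least two")
  gr <- tibble::tibble(behaviour_id = "1", barrier_id = c("a", "b"),
                       influence_rank = 1:2, difficulty_rank = c(NA, 2L))
  expect_error(classify_dataset(gr), "missing an attribute")
})

test_that("classify_dataset accepts long group_ranking objects", {
  pm_i <- pairwise_matrix_from_orders(rep(list(c("a", "b", "c")), 3),
                                      behaviour_id = "1",
                                      attribute = "influence")
  pm_d <- pairwise_matrix_from_orders(rep(list(c("c", "b", "a")), 3),
                                      behaviour_id = "1",
                                      attribute = "difficulty")
  res <- classify_dataset(list(aggregate(pm_i), aggregate(pm_d)))
  expect_equal(as.character(res[["1"]]$labels$desirability), rep("desirable", 3))
})
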