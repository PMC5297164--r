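# Pairwise-majority tallies and the voting rules (Schulze default, Copeland,
# exact Kemeny-Young).

test_that("pairwise matrices tally strict preferences correctly", {
  pm <- pairwise_matrix_from_orders(rep(list(c("a", "b", "c")), 3))
  expect_equal(pm$prefer["a", "b"], 3L)
  expect_equal(pm$prefer["a", "c"], 3L)
  expect_equal(pm$prefer["b", "c"], 3L)
  expect_equal(pm$prefer["b", "a"], 0L)
  expect_equal(sum(diag(pm$prefer)), 0L)

  pm2 <- pairwise_matrix_from_orders(list(c("a", "b"), c("b", "a")))
  expect_equal(pm2$prefer["a", "b"], 1L)
  expect_equal(pm2$prefer["b", "a"], 1L)

  # perfect three-ballot cycle: every off-diagonal margin is 2 vs 1
  cyc <- pairwise_matrix_from_orders(
    list(c("a", "b", "c"), c("b", "c", "a"), c("c", "a", "b")))
  off <- cyc$prefer[upper.tri(cyc$prefer) | lower.tri(cyc$prefer)]
  expect_setequal(unique(off), c(1L, 2L))
  expect_equal(cyc$prefer["a", "b"], 2L)
  expect_equal(cyc$prefer["b", "c"], 2L)
  expect_equal(cyc$prefer["c", "a"], 2L)
})

test_that("pairwise matrices from a survey use the canonical direction", {
  # raw influence rank 1 = most influential, so b1 ranked 1 beats b2 ranked 2
  ds <- toy_dataset(list(c("b1", "b2", "b3")))
  pm <- pairwise_matrix(ds, "1", "influence")
  expect_equal(pm$prefer["b1", "b2"], 1L)
  expect_equal(pm$prefer["b2", "b1"], 0L)
  expect_error(pairwise_matrix(ds, "1", "difficulty"), "no ballots")
})

test_that("pair totals always equal the ballot count", {
  set.seed(81)
  for (rep in 1:25) {
    n <- sample(2:7, 1)
    nb <- sample(2:9, 1)
    pm <- pairwise_matrix_from_orders(random_orders(n, nb))
    sums <- pm$prefer + t(pm$prefer)
    expect_true(all(sums[upper.tri(sums)] == nb))
  }
})

test_that("a unanimous panel reproduces its shared ballot under every method", {
  set.seed(82)
  for (method in c("schulze", "copeland", "kemeny")) {
    ord <- sample(letters[1:6])
    pm <- pairwise_matrix_from_orders(rep(list(ord), 5))
    g <- aggregate(pm, method = method)
    expect_equal(g$barrier_id, ord)
    expect_equal(g$rank, 6:1)
  }
})

test_that("a perfect cycle is fully tied under the default method", {
  cyc <- pairwise_matrix_from_orders(
    list(c("a", "b", "c"), c("b", "c", "a"), c("c", "a", "b")))
  g <- aggregate(cyc)
  expect_equal(g$rank, rep(1L, 3))
  # hand-computed beatpath strengths: every strongest path has strength 2,
  # so no item beats any other
  strength <- paretorank:::schulze_wins(cyc$prefer)
  expect_equal(unname(strength), rep(0, 3))
})

test_that("ties share the bottom-up competition rank and a clear winner gets n", {
  # a unanimously first, b/c/d in a perfect cycle below
  pm <- pairwise_matrix_from_orders(list(
    c("a", "b", "c", "d"), c("a", "c", "d", "b"), c("a", "d", "b", "c")))
  g <- aggregate(pm)
  expect_equal(g$rank[g$barrier_id == "a"], 4L)
  expect_equal(g$rank[g$barrier_id != "a"], rep(1L, 3))
})

test_that("two items with a 2-1 majority order as the majority says", {
  pm <- pairwise_matrix_from_orders(list(c("a", "b"), c("a", "b"), c("b", "a")))
  for (method in c("schulze", "copeland", "kemeny")) {
    g <- aggregate(pm, method = method)
    expect_gt(g$rank[g$barrier_id == "a"], g$rank[g$barrier_id == "b"])
  }
})

test_that("exact Kemeny equals the enumeration oracle on random instances", {
  set.seed(83)
  for (rep in 1:40) {
    n <- sample(2:5, 1)
    items <- letters[seq_len(n)]
    ballots <- random_orders(n, sample(c(3, 5, 7), 1), items = items)
    pm <- pairwise_matrix_from_orders(ballots, items = items)
    g <- aggregate_kemeny_exact(pm)
    got <- g$barrier_id[order(-g$rank)]
    oracle <- kemeny_oracle(ballots, items)
    # the package returns the lexicographically smallest co-optimal order
    expect_equal(got, lex_min_order(oracle$orders))
    # and its score is optimal
    expect_equal(sum(vapply(ballots, function(bl)
      kendall_disagreement(got, bl), integer(1))), oracle$score)
  }
})

test_that("kemeny helpers enforce their size limits", {
  pm <- pairwise_matrix_from_orders(list(letters[1:10]), items = letters[1:10])
  expect_error(aggregate_kemeny_exact(pm), "9 items")
  expect_error(kemeny_optima(pm), "8 items")
  expect_error(aggregate(pm, method = "borda"))
})

test_that("pairwise unanimity is never inverted by any method", {
  set.seed(84)
  for (rep in 1:30) {
    n <- sample(3:6, 1)
    items <- letters[seq_len(n)]
    # force unanimity on one pair: 'a' always immediately above 'b'
    ballots <- lapply(seq_len(5), function(i) {
      ord <- sample(setdiff(items, "b"))
      append(ord, "b", after = match("a", ord))
    })
    pm <- pairwise_matrix_from_orders(ballots, items = items)
    for (method in c("schulze", "copeland", "kemeny")) {
      g <- aggregate(pm, method = method)
      expect_false(g$rank[g$barrier_id == "b"] > g$rank[g$barrier_id == "a"])
    }
  }
})

test_that("a Condorcet winner is uniquely top under schulze and kemeny", {
  set.seed(85)
  found <- 0
  while (found < 20) {
    n <- sample(3:6, 1)
    pm <- pairwise_matrix_from_orders(random_orders(n, 7))
    wins <- rowSums(pm$prefer > t(pm$prefer))
    cw <- which(wins == n - 1)
    if (length(cw) != 1) next
    found <- found + 1
    for (method in c("schulze", "kemeny")) {
      g <- aggregate(pm, method = method)
      top <- g$barrier_id[g$rank == max(g$rank)]
      expect_equal(top, pm$items[cw])
    }
  }
})

test_that("relabelling barriers permutes the group ranking identically", {
  set.seed(86)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    items <- letters[seq_len(n)]
    ballots <- random_orders(n, 5, items = items)
    relabel <- setNames(sample(LETTERS[seq_len(n)]), items)
    g1 <- aggregate(pairwise_matrix_from_orders(ballots, items = items))
    g2 <- aggregate(pairwise_matrix_from_orders(
      lapply(ballots, function(b) unname(relabel[b])),
      items = unname(relabel[items])))
    r1 <- setNames(g1$rank, relabel[g1$barrier_id])
    r2 <- setNames(g2$rank, g2$barrier_id)
    expect_equal(r1[sort(names(r1))], r2[sort(names(r2))])
  }
})

test_that("ballot order and respondent identity never matter", {
  set.seed(87)
  ballots <- random_orders(5, 8)
  g1 <- aggregate(pairwise_matrix_from_orders(ballots))
  g2 <- aggregate(pairwise_matrix_from_orders(sample(ballots)))
  expect_equal(g1, g2)
})

test_that("raising an item in one ballot never lowers its schulze rank", {
  set.seed(88)
  for (rep in 1:60) {
    n <- sample(3:6, 1)
    ballots <- random_orders(n, 7)
    pm <- pairwise_matrix_from_orders(ballots)
    g <- aggregate(pm)
    # pick a ballot where some item is not already first and promote it
    b <- sample(length(ballots), 1)
    pos <- sample(2:n, 1)
    item <- ballots[[b]][pos]
    ballots[[b]][c(pos - 1, pos)] <- ballots[[b]][c(pos, pos - 1)]
    g2 <- aggregate(pairwise_matrix_from_orders(ballots))
    expect_gte(g2$rank[g2$barrier_id == item], g$rank[g$barrier_id == item])
  }
})

test_that("aggregate_dataset emits one wide row per barrier", {
  cat9 <- stroke_catalogue()
  sim <- simulate_panel(panel_config(cat9, dispersion = 1e6, seed = 5))
  gr <- aggregate_dataset(sim)
  expect_equal(nrow(gr), 53)
  expect_true(all(c("influence_rank", "difficulty_rank") %in% names(gr)))
  # noiseless panel: group ranks equal the truth (catalogue order, best first)
  for (bid in cat9$behaviours$behaviour_id) {
    rows <- gr[gr$behaviour_id == bid, ]
    nb <- nrow(rows)
    expect_equal(rows$influence_rank[match(behaviour_barriers(cat9, bid),
                                           rows$barrier_id)], nb:1)
  }
})

test_that("group-rank files round-trip and are validated", {
  cat9 <- stroke_catalogue()
  gr <- stroke_group_ranks(cat9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_group_ranks(gr, f)
  back <- read_group_ranks(cat9, f)
  expect_equal(back, gr)

  bad <- gr
  bad$influence_rank[1] <- 99L
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, f2)
  expect_error(read_group_ranks(cat9, f2), "rank outside")

  f3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(gr[-1, ], f3)
  expect_error(read_group_ranks(cat9, f3), "incomplete")
})
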