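# Aggregation of individual ballots into one tie-permitting group ranking per
# behaviour x attribute, via Condorcet-consistent voting rules on the
# pairwise-majority graph. Default rule: Schulze's beatpath method. Copeland
# and exact Kemeny-Young are provided as alternatives; all three emit the same
# group-ranking structure.

#' Pairwise-majority matrix of a behaviour's ballots
#'
#' `prefer[a, b]` counts the ballots ranking barrier `a` strictly better than
#' barrier `b` in the canonical direction (more influential / less difficult).
#' Since ballots are tie-free, `prefer[a, b] + prefer[b, a]` equals the number
#' of ballots for every pair.
#'
#' @param dataset A [survey_dataset()].
#' @param behaviour_id Behaviour whose ballots to tally.
#' @param attribute `"influence"` or `"difficulty"`.
#' @return An object of class `pairwise_matrix`: list with `behaviour_id`,
#'   `attribute`, `items` (barrier ids, catalogue order), `prefer` (integer
#'   matrix), `n_ballots`.
#' @export
pairwise_matrix <- function(dataset, behaviour_id, attribute) {
  stopifnot(inherits(dataset, "survey_dataset"))
  attribute <- match.arg(attribute, ATTRIBUTES)
  items <- behaviour_barriers(dataset$catalogue, behaviour_id)
  nb <- length(items)
  rows <- dataset$ballots |>
    filter(.data$behaviour_id == !!behaviour_id, .data$attribute == !!attribute)
  if (nrow(rows) == 0) {
    abort(sprintf("no ballots for behaviour %s, attribute %s",
                  behaviour_id, attribute))
  }
  rows$canonical <- canonicalize_rank(rows$rank, nb, attribute)
  prefer <- matrix(0L, nb, nb, dimnames = list(items, items))
  for (rid in unique(rows$respondent_id)) {
    one <- rows[rows$respondent_id == rid, ]
    r <- one$canonical[match(items, one$barrier_id)]
    prefer <- prefer + outer(r, r, ">")
  }
  new_pairwise_matrix(prefer, items, behaviour_id, attribute)
}

#' Pairwise-majority matrix from a list of rankings
#'
#' Lower-level constructor used for simulation studies and property tests:
#' each element of `orders` is one ballot given directly as a total order of
#' item labels, best first (most influential / least difficult first).
#'
#' @param orders List of character vectors, each a permutation of the same
#'   item set, best item first.
#' @param items Optional item ordering for the matrix; defaults to the first
#'   ballot's order sorted lexicographically.
#' @param behaviour_id,attribute Optional metadata tags.
#' @return A `pairwise_matrix`.
#' @export
pairwise_matrix_from_orders <- function(orders, items = NULL,
                                        behaviour_id = NA_character_,
                                        attribute = NA_character_) {
  if (!length(orders)) abort("need at least one ballot")
  if (is.null(items)) items <- sort(orders[[1]])
  nb <- length(items)
  prefer <- matrix(0L, nb, nb, dimnames = list(items, items))
  for (ord in orders) {
    if (!setequal(ord, items) || length(ord) != nb) {
      abort("every ballot must be a permutation of the item set")
    }
    r <- nb + 1L - match(items, ord)  # canonical: best item -> nb
    prefer <- prefer + outer(r, r, ">")
  }
  new_pairwise_matrix(prefer, items, behaviour_id, attribute)
}

new_pairwise_matrix <- function(prefer, items, behaviour_id, attribute) {
  structure(
    list(behaviour_id = behaviour_id, attribute = attribute, items = items,
         prefer = prefer, n_ballots = prefer[1, 2] + prefer[2, 1]),
    class = "pairwise_matrix"
  )
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix> behaviour %s / %s: %d items, %d ballots\n",
              x$behaviour_id, x$attribute, length(x$items), x$n_ballots))
  print(x$prefer)
  invisible(x)
}

#' Aggregate a pairwise-majority matrix into a group ranking
#'
#' Produces a total preorder over the barriers, reported as tie-sharing
#' integer ranks in the canonical direction (higher value = more influential /
#' less difficult; the unique best barrier, when there is one, gets rank
#' `n_barriers`). Ties share the competition rank of their indifference class
#' counted from the worst class (rank = 1 + number of strictly worse
#' barriers).
#'
#' Methods: `"schulze"` (default) ranks by beatpath wins on the
#' pairwise-majority graph with winning-votes strengths — graph-theoretic,
#' Condorcet-consistent and tie-friendly; `"copeland"` ranks by pairwise wins
#' minus losses; `"kemeny"` calls [aggregate_kemeny_exact()]. A Condorcet
#' winner is always uniquely top under schulze and kemeny, and a unanimous
#' panel always reproduces its shared ballot under every method.
#'
#' @param x A [pairwise_matrix()].
#' @param method `"schulze"`, `"copeland"` or `"kemeny"`.
#' @param ... Unused.
#' @return A `group_ranking`: tibble with columns `behaviour_id`, `attribute`,
#'   `barrier_id`, `rank`, plus a `method` attribute.
#' @examples
#' pm <- pairwise_matrix_from_orders(list(c("a", "b", "c"), c("a", "c", "b")))
#' aggregate(pm)
#' @export
aggregate.pairwise_matrix <- function(x, method = c("schulze", "copeland", "kemeny"),
                                      ...) {
  method <- match.arg(method)
  if (method == "kemeny") {
    return(aggregate_kemeny_exact(x))
  }
  scores <- switch(method,
    schulze = schulze_wins(x$prefer),
    copeland = copeland_scores(x$prefer)
  )
  new_group_ranking(x, ranks_from_scores(scores), method)
}

# Beatpath (widest-path) strengths with winning-votes edge weights, then one
# "win" per opponent beaten in the beatpath comparison. The beatpath relation
# is transitive, so win counts induce a total preorder consistent with it.
schulze_wins <- function(prefer) {
  nb <- nrow(prefer)
  strength <- matrix(0, nb, nb)
  win <- prefer > t(prefer)
  strength[win] <- prefer[win]
  for (k in seq_len(nb)) {
    for (i in seq_len(nb)) {
      if (i == k) next
      cap <- pmin(strength[i, k], strength[k, ])
      strength[i, ] <- pmax(strength[i, ], cap)
    }
  }
  diag(strength) <- 0
  rowSums(strength > t(strength))
}

copeland_scores <- function(prefer) {
  win <- prefer > t(prefer)
  rowSums(win) - colSums(win)
}

# Bottom-up competition ranks: 1 + number of strictly worse items; ties share.
ranks_from_scores <- function(scores) {
  vapply(scores, function(s) 1L + sum(scores < s), integer(1))
}

new_group_ranking <- function(pm, ranks, method) {
  out <- tibble(
    behaviour_id = pm$behaviour_id,
    attribute = pm$attribute,
    barrier_id = pm$items,
    rank = as.integer(ranks)
  ) |>
    arrange(desc(.data$rank), .data$barrier_id)
  attr(out, "method") <- method
  class(out) <- c("group_ranking", class(out))
  out
}

#' Exact Kemeny-Young consensus ranking
#'
#' Finds a total order minimising the summed pairwise disagreement with the
#' ballots (the Kemeny score), by dynamic programming over item subsets
#' (feasible up to 9 items; each behaviour here has at most 9 barriers).
#' Among co-optimal orders the lexicographically smallest by barrier id is
#' returned, so the result is deterministic. The output is a strict order
#' (ranks `n..1`, no ties).
#'
#' @param x A [pairwise_matrix()].
#' @return A `group_ranking` (see [aggregate.pairwise_matrix()]).
#' @export
aggregate_kemeny_exact <- function(x) {
  stopifnot(inherits(x, "pairwise_matrix"))
  nb <- length(x$items)
  if (nb > 9) {
    abort("kemeny exact is limited to 9 items; use method = 'schulze'")
  }
  ord <- kemeny_dp_order(x$prefer, x$items)
  ranks <- (nb:1L)[match(x$items, ord)]
  new_group_ranking(x, ranks, "kemeny")
}

# Subset DP on the linear ordering problem. State = set of items still to be
# placed (as a bitmask); placing item i at the top of that set costs the
# ballots preferring any remaining j over i. g[S] = min_i cost(i, S) +
# g[S \ i]. Reconstruction picks the smallest item id among optimal choices.
kemeny_dp_order <- function(prefer, items) {
  nb <- length(items)
  nmask <- bitwShiftL(1L, nb)
  g <- rep(0, nmask)
  bit <- bitwShiftL(1L, seq_len(nb) - 1L)
  members <- lapply(seq_len(nmask) - 1L, function(m) which(bitwAnd(m, bit) != 0L))
  for (m in seq_len(nmask - 1L)) {          # mask value m, skip empty set 0
    s <- members[[m + 1L]]
    best <- Inf
    for (i in s) {
      rest <- setdiff(s, i)
      cost <- sum(prefer[rest, i]) + g[m - bit[i] + 1L]
      if (cost < best) best <- cost
    }
    g[m + 1L] <- best
  }
  # reconstruct top -> bottom, lexicographic tie-break on item label
  ord <- character(0)
  m <- nmask - 1L
  while (m > 0L) {
    s <- members[[m + 1L]]
    cand <- s[vapply(s, function(i) {
      rest <- setdiff(s, i)
      sum(prefer[rest, i]) + g[m - bit[i] + 1L] == g[m + 1L]
    }, logical(1))]
    pick <- cand[order(items[cand])][1]
    ord <- c(ord, items[pick])
    m <- m - bit[pick]
  }
  ord
}

#' All Kemeny-optimal orders by exhaustive enumeration
#'
#' Enumerates every permutation of the items (limited to 8), scores each by
#' total pairwise disagreement, and returns all co-optimal orders. Mainly
#' useful to detect whether the Kemeny optimum is unique on small instances.
#'
#' @param x A [pairwise_matrix()].
#' @return List with `score` (minimal Kemeny score) and `orders` (list of
#'   character vectors, best first).
#' @export
kemeny_optima <- function(x) {
  stopifnot(inherits(x, "pairwise_matrix"))
  nb <- length(x$items)
  if (nb > 8) abort("enumeration is limited to 8 items")
  perms <- permutations_of(nb)
  upper <- upper.tri(matrix(0, nb, nb))
  scores <- apply(perms, 1, function(p) {
    m <- x$prefer[p, p]
    sum(t(m)[upper])  # ballots preferring a lower-placed item over a higher one
  })
  best <- min(scores)
  list(score = best,
       orders = lapply(which(scores == best), function(i) x$items[perms[i, ]]))
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

#' Aggregate every behaviour and attribute of a dataset
#'
#' @param dataset A [survey_dataset()].
#' @param method Voting rule passed to [aggregate.pairwise_matrix()].
#' @return A wide tibble with columns `behaviour_id`, `barrier_id`,
#'   `influence_rank`, `difficulty_rank` (behaviours lacking ballots for an
#'   attribute get `NA` there).
#' @export
aggregate_dataset <- function(dataset, method = "schulze") {
  combos <- distinct(dataset$ballots, .data$behaviour_id, .data$attribute)
  long <- bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    pm <- pairwise_matrix(dataset, combos$behaviour_id[i], combos$attribute[i])
    as_tibble(aggregate(pm, method = method))
  }))
  group_ranks_table(long)
}

#' Reshape long group rankings to the wide reporting layout
#'
#' @param rankings A `group_ranking`, a list of them, or their row-bound
#'   tibble.
#' @return Wide tibble: `behaviour_id`, `barrier_id`, `influence_rank`,
#'   `difficulty_rank`.
#' @export
group_ranks_table <- function(rankings) {
  if (inherits(rankings, "group_ranking")) rankings <- list(rankings)
  if (is.list(rankings) && !is.data.frame(rankings)) {
    rankings <- bind_rows(lapply(rankings, as_tibble))
  }
  rankings |>
    as_tibble() |>
    tidyr::pivot_wider(id_cols = c("behaviour_id", "barrier_id"),
                       names_from = "attribute", values_from = "rank") |>
    rename(influence_rank = dplyr::any_of("influence"),
           difficulty_rank = dplyr::any_of("difficulty")) |>
    arrange(.data$behaviour_id, .data$barrier_id)
}

#' Write a wide group-ranking table to CSV
#'
#' @param group_ranks Wide table from [aggregate_dataset()] or
#'   [group_ranks_table()].
#' @param path Output path.
#' @return `group_ranks`, invisibly.
#' @export
write_group_ranks <- function(group_ranks, path) {
  readr::write_csv(group_ranks, path, progress = FALSE)
  invisible(group_ranks)
}

#' Read a wide group-ranking table
#'
#' Accepts a file in the reporting layout (`behaviour_id`, `barrier_id`,
#' `influence_rank`, `difficulty_rank`, optionally a `desirability` column),
#' validating that every behaviour's barrier set is complete and all ranks lie
#' in `1..n_barriers`. This is the "precomputed group ranks" entry point used
#' when raw ballots are unavailable.
#'
#' @param catalogue A [barrier_catalogue()].
#' @param path Path to the delimited file.
#' @return A wide tibble of group ranks.
#' @export
read_group_ranks <- function(catalogue, path) {
  gr <- read_delim_auto(path)
  required <- c("behaviour_id", "barrier_id", "influence_rank", "difficulty_rank")
  missing_cols <- setdiff(required, names(gr))
  if (length(missing_cols)) {
    abort(sprintf("group-rank table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  gr$influence_rank <- as.integer(gr$influence_rank)
  gr$difficulty_rank <- as.integer(gr$difficulty_rank)
  for (bid in unique(gr$behaviour_id)) {
    rows <- gr[gr$behaviour_id == bid, ]
    expected <- behaviour_barriers(catalogue, bid)
    if (!setequal(rows$barrier_id, expected) || nrow(rows) != length(expected)) {
      abort(sprintf("behaviour %s: barrier set incomplete or duplicated", bid))
    }
    nb <- length(expected)
    if (any(rows$influence_rank < 1 | rows$influence_rank > nb) ||
        any(rows$difficulty_rank < 1 | rows$difficulty_rank > nb)) {
      abort(sprintf("behaviour %s: rank outside 1..%d", bid, nb))
    }
  }
  gr
}
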