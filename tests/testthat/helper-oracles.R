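# Independent oracles and in-code fixture builders. Everything here is coded
# separately from the package internals so that tests compare two independent
# routes to the same answer.

# --- permutations (independent of paretorank:::permutations_of) -------------

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# --- Kemeny enumeration oracle ----------------------------------------------

# Disagreements of a candidate group order with one ballot, counted directly
# from positions (not via a pairwise matrix).
kendall_disagreement <- function(order, ballot) {
  n <- length(order)
  s <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # group places order[i] above order[j]; ballot disagrees if it ranks
      # order[j] better (earlier) than order[i]
      if (match(order[j], ballot) < match(order[i], ballot)) s <- s + 1L
    }
  }
  s
}

kemeny_oracle <- function(ballots, items) {
  ps <- all_perms(items)
  scores <- vapply(ps, function(p) {
    sum(vapply(ballots, function(bl) kendall_disagreement(p, bl), integer(1)))
  }, integer(1))
  best <- min(scores)
  list(score = best, orders = ps[scores == best])
}

lex_min_order <- function(orders) {
  keys <- vapply(orders, paste, character(1), collapse = "\r")
  orders[[order(keys)[1]]]
}

# --- all-pairs dominance oracle ---------------------------------------------

classify_oracle <- function(points) {
  n <- nrow(points)
  dom <- function(i, j) {
    ge <- points$influence_rank[i] >= points$influence_rank[j] &&
      points$difficulty_rank[i] >= points$difficulty_rank[j]
    gt <- points$influence_rank[i] > points$influence_rank[j] ||
      points$difficulty_rank[i] > points$difficulty_rank[j]
    ge && gt
  }
  labels <- character(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    most <- TRUE
    for (j in seq_len(n)) {
      if (i == j) next
      if (dom(j, i)) dominated <- TRUE
      tie <- points$influence_rank[i] == points$influence_rank[j] &&
        points$difficulty_rank[i] == points$difficulty_rank[j]
      if (!dom(i, j) && !tie) most <- FALSE
    }
    labels[i] <- if (most) "most_desirable"
      else if (dominated) "least_desirable"
      else "desirable"
  }
  labels
}

# --- independent percentile (linear interpolation between closest ranks) ----

quantile_interp_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# --- in-code fixtures --------------------------------------------------------

toy_catalogue <- function(n, behaviour_id = "1", groups = "EN") {
  barrier_catalogue(tibble::tibble(
    behaviour_id = behaviour_id,
    behaviour_name = paste("behaviour", behaviour_id),
    barrier_id = paste0("b", seq_len(n)),
    barrier_description = paste("barrier", seq_len(n)),
    eligible_groups = groups
  ))
}

# Build a one-behaviour dataset from ballots given as canonical orders
# (best first); converts to the raw elicitation direction.
toy_dataset <- function(orders, attribute = "influence", catalogue = NULL) {
  n <- length(orders[[1]])
  if (is.null(catalogue)) catalogue <- toy_catalogue(n)
  resp <- tibble::tibble(respondent_id = paste0("r", seq_along(orders)),
                         group = "EN")
  ballots <- dplyr::bind_rows(lapply(seq_along(orders), function(i) {
    ord <- orders[[i]]
    pos <- seq_along(ord)
    raw <- if (attribute == "influence") pos else n + 1L - pos
    tibble::tibble(respondent_id = paste0("r", i), behaviour_id = "1",
                   attribute = attribute, barrier_id = ord, rank = raw)
  }))
  survey_dataset(catalogue, resp, ballots)
}

random_orders <- function(n_items, n_ballots, items = letters[seq_len(n_items)]) {
  lapply(seq_len(n_ballots), function(i) sample(items))
}

random_points <- function(n, max_rank = n) {
  tibble::tibble(
    barrier_id = paste0("p", seq_len(n)),
    influence_rank = sample.int(max_rank, n, replace = TRUE),
    difficulty_rank = sample.int(max_rank, n, replace = TRUE)
  )
}

stroke_catalogue <- function() {
  read_catalogue(paretorank_example("stroke_catalogue.csv"))
}

stroke_group_ranks <- function(catalogue = stroke_catalogue()) {
  read_group_ranks(catalogue, paretorank_example("stroke_group_ranks.csv"))
}

# --- CLI runner ---------------------------------------------------------------

run_cli <- function(...) {
  script <- system.file("cli", "paretorank.R", package = "paretorank")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(script, ...), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
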