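# Classification of barriers into most desirable / desirable / least
# desirable targets from the two group ranks, by weak Pareto dominance.
#
# Dominance is weak: a dominates b when a is at least as good on both
# attributes and strictly better on at least one. This (not strict two-axis
# dominance) is what reproduces the published classifications, where a
# barrier tied on one axis but beaten on the other is "least desirable".

#' Weak Pareto dominance between two barriers
#'
#' `a` dominates `b` iff `a` is at least as influential AND at least as easy
#' to overcome, with strict advantage on at least one attribute. Exact ties on
#' both attributes never dominate (in either direction).
#'
#' @param a,b Numeric vectors `c(influence_rank, difficulty_rank)` in the
#'   canonical direction, or one-row data frames with `influence_rank` and
#'   `difficulty_rank` columns.
#' @return Logical scalar.
#' @examples
#' dominates(c(6, 4), c(5, 4))  # more influential, equally difficult -> TRUE
#' dominates(c(8, 1), c(2, 8))  # incomparable -> FALSE
#' @export
dominates <- function(a, b) {
  a <- as_point(a)
  b <- as_point(b)
  all(a >= b) && any(a > b)
}

as_point <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1)
    p <- c(p$influence_rank, p$difficulty_rank)
  }
  stopifnot(is.numeric(p), length(p) == 2)
  p
}

#' Classify one behaviour's barriers by desirability to target
#'
#' Applies the three pre-specified principles to the group ranks:
#' \enumerate{
#'   \item a barrier that weakly dominates every other barrier (at least as
#'     good on both attributes, strictly better on at least one, against each
#'     competitor) is \emph{most desirable};
#'   \item a barrier with no other barrier both more influential and less
#'     difficult (i.e. not weakly dominated by anything) is \emph{desirable};
#'   \item a barrier weakly dominated by some other barrier is \emph{least
#'     desirable}.
#' }
#' Barriers exactly tied on both attributes share a label; in particular a
#' class of exact ties that dominates all outsiders shares `most_desirable`
#' (an extrapolation — the published data contain no such case).
#'
#' @param points Data frame with columns `barrier_id`, `influence_rank`,
#'   `difficulty_rank` (canonical direction), at least two rows.
#' @param behaviour_id Optional behaviour tag carried into the result.
#' @return An object of class `desirability_result`: list with
#'   `behaviour_id`; `labels`, a tibble adding a `desirability` column to
#'   `points`; and `dominance_edges`, a tibble of all (dominator, dominated)
#'   pairs. Every least-desirable barrier has at least one recorded dominator;
#'   most-desirable and desirable barriers have none.
#' @export
classify_barriers <- function(points, behaviour_id = NA_character_) {
  points <- as_tibble(points)
  required <- c("barrier_id", "influence_rank", "difficulty_rank")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols)) {
    abort(sprintf("points are missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(points) < 2) abort("need at least two barriers to classify")
  if (anyDuplicated(points$barrier_id)) {
    abort(sprintf("duplicate barrier_id: %s",
                  paste(unique(points$barrier_id[duplicated(points$barrier_id)]),
                        collapse = ", ")))
  }

  inf <- points$influence_rank
  dif <- points$difficulty_rank
  ge_both <- outer(inf, inf, ">=") & outer(dif, dif, ">=")
  gt_any <- outer(inf, inf, ">") | outer(dif, dif, ">")
  dom <- ge_both & gt_any                      # dom[i, j]: i dominates j
  tie <- outer(inf, inf, "==") & outer(dif, dif, "==")
  diag(tie) <- FALSE

  dominated <- apply(dom, 2, any)
  # most desirable: dominates (or exactly ties with) every other barrier
  most <- vapply(seq_len(nrow(points)), function(i) {
    others <- setdiff(seq_len(nrow(points)), i)
    all(dom[i, others] | tie[i, others])
  }, logical(1))

  label <- ifelse(most, "most_desirable",
                  ifelse(dominated, "least_desirable", "desirable"))

  idx <- which(dom, arr.ind = TRUE)
  edges <- tibble(
    dominator = points$barrier_id[idx[, 1]],
    dominated = points$barrier_id[idx[, 2]]
  ) |>
    arrange(.data$dominator, .data$dominated)

  labels <- points
  labels$desirability <- factor(label, levels = DESIRABILITY_LEVELS)
  structure(
    list(behaviour_id = behaviour_id, labels = labels, dominance_edges = edges),
    class = "desirability_result"
  )
}

#' @export
print.desirability_result <- function(x, ...) {
  cat(sprintf("<desirability_result> behaviour %s\n", x$behaviour_id))
  print(as.data.frame(x$labels))
  invisible(x)
}

#' Classify every behaviour of a group-ranking table
#'
#' @param group_ranks Either a wide table (`behaviour_id`, `barrier_id`,
#'   `influence_rank`, `difficulty_rank`) as produced by
#'   [aggregate_dataset()] / [read_group_ranks()], or a list of long
#'   `group_ranking` objects covering both attributes per behaviour.
#' @return Named list of [classify_barriers()] results, one per behaviour.
#' @examples
#' cat9 <- read_catalogue(paretorank_example("stroke_catalogue.csv"))
#' gr <- read_group_ranks(cat9, paretorank_example("stroke_group_ranks.csv"))
#' res <- classify_dataset(gr)
#' res[["4"]]  # temperature: one most-desirable barrier
#' @export
classify_dataset <- function(group_ranks) {
  if (!is.data.frame(group_ranks)) {
    group_ranks <- group_ranks_table(group_ranks)
  }
  required <- c("behaviour_id", "barrier_id", "influence_rank", "difficulty_rank")
  missing_cols <- setdiff(required, names(group_ranks))
  if (length(missing_cols)) {
    abort(sprintf("group ranks are missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  incomplete <- group_ranks |>
    group_by(.data$behaviour_id) |>
    summarise(bad = anyNA(.data$influence_rank) || anyNA(.data$difficulty_rank),
              .groups = "drop")
  if (any(incomplete$bad)) {
    abort(sprintf("behaviour(s) missing an attribute ranking: %s",
                  paste(incomplete$behaviour_id[incomplete$bad], collapse = ", ")))
  }
  ids <- unique(group_ranks$behaviour_id)
  out <- lapply(ids, function(bid) {
    classify_barriers(group_ranks[group_ranks$behaviour_id == bid,
                                  c("barrier_id", "influence_rank",
                                    "difficulty_rank")],
                      behaviour_id = bid)
  })
  names(out) <- ids
  out
}

#' Flatten classification results into the reporting table
#'
#' @param results List of `desirability_result` (from [classify_dataset()]).
#' @return Tibble mirroring the published layout: `behaviour_id`,
#'   `barrier_id`, `influence_rank`, `difficulty_rank`, `desirability`.
#' @export
desirability_table <- function(results) {
  if (inherits(results, "desirability_result")) results <- list(results)
  bind_rows(lapply(results, function(r) {
    out <- r$labels
    out$behaviour_id <- r$behaviour_id
    out$desirability <- as.character(out$desirability)
    out[, c("behaviour_id", "barrier_id", "influence_rank", "difficulty_rank",
            "desirability")]
  }))
}

#' Write a desirability table to CSV
#'
#' @param results List of `desirability_result` or a [desirability_table()].
#' @param path Output path.
#' @return The written tibble, invisibly.
#' @export
write_desirability <- function(results, path) {
  tab <- if (is.data.frame(results)) results else desirability_table(results)
  readr::write_csv(tab, path, progress = FALSE)
  invisible(tab)
}
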