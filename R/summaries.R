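# Per-barrier summaries of the individual ballots: median rank and
# interquartile range on the canonical reporting direction.

#' Convert a raw elicited rank to the canonical reporting direction
#'
#' Ballots are elicited with "higher rank = lower influence" and "higher rank
#' = least difficult". Reporting uses the canonical direction "higher = more
#' influential" and "higher = less difficult": influence ranks are therefore
#' reversed (`n_barriers + 1 - raw`), difficulty ranks are already canonical
#' (identity).
#'
#' @param raw_rank Integer rank(s) in `1..n_barriers`.
#' @param n_barriers Scale maximum (number of barriers of the behaviour).
#' @param attribute `"influence"` or `"difficulty"`.
#' @return Integer vector of canonical ranks.
#' @examples
#' canonicalize_rank(1, 6, "influence")   # most influential -> 6
#' canonicalize_rank(4, 8, "difficulty")  # identity -> 4
#' @export
canonicalize_rank <- function(raw_rank, n_barriers, attribute) {
  attribute <- match.arg(attribute, ATTRIBUTES)
  raw_rank <- as.integer(raw_rank)
  if (any(raw_rank < 1L | raw_rank > n_barriers)) {
    abort(sprintf("rank out of range 1..%d", n_barriers))
  }
  if (attribute == "influence") n_barriers + 1L - raw_rank else raw_rank
}

#' Median and IQR of canonical ranks per barrier
#'
#' Summarises the individual ballots of one behaviour/attribute: the median
#' and interquartile range (25th/75th percentiles, linear interpolation —
#' [stats::quantile()] type 7) of the canonical ranks across the ballots
#' present. Barriers are listed in order of descending median (ties broken by
#' barrier id), i.e. most influential / least difficult first.
#'
#' @param dataset A [survey_dataset()].
#' @param behaviour_id Behaviour to summarise.
#' @param attribute `"influence"` or `"difficulty"`.
#' @return A tibble with columns `barrier_id`, `attribute`, `median`,
#'   `iqr_low`, `iqr_high`, `n_ballots`, `direction`.
#' @export
summarize_ranks <- function(dataset, behaviour_id, attribute) {
  stopifnot(inherits(dataset, "survey_dataset"))
  attribute <- match.arg(attribute, ATTRIBUTES)
  nb <- n_barriers(dataset$catalogue, behaviour_id)
  rows <- dataset$ballots |>
    filter(.data$behaviour_id == !!behaviour_id, .data$attribute == !!attribute)
  if (nrow(rows) == 0) {
    abort(sprintf("no ballots for behaviour %s, attribute %s",
                  behaviour_id, attribute))
  }
  rows$canonical <- canonicalize_rank(rows$rank, nb, attribute)
  direction <- if (attribute == "influence") {
    "higher = more influential"
  } else {
    "higher = less difficult"
  }
  rows |>
    group_by(barrier_id = .data$barrier_id) |>
    summarise(
      attribute = !!attribute,
      median = median(.data$canonical),
      iqr_low = unname(quantile(.data$canonical, 0.25, type = 7)),
      iqr_high = unname(quantile(.data$canonical, 0.75, type = 7)),
      n_ballots = n(),
      direction = !!direction,
      .groups = "drop"
    ) |>
    arrange(desc(.data$median), .data$barrier_id)
}

#' Summaries for every behaviour and attribute with ballots
#'
#' @param dataset A [survey_dataset()].
#' @return A tibble of [summarize_ranks()] results stacked, with a leading
#'   `behaviour_id` column.
#' @export
summarize_all_ranks <- function(dataset) {
  combos <- distinct(dataset$ballots, .data$behaviour_id, .data$attribute)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    res <- summarize_ranks(dataset, combos$behaviour_id[i], combos$attribute[i])
    res$behaviour_id <- combos$behaviour_id[i]
    res
  })
  bind_rows(out) |>
    select("behaviour_id", "barrier_id", "attribute", "median", "iqr_low",
           "iqr_high", "n_ballots", "direction") |>
    arrange(.data$behaviour_id, .data$attribute, desc(.data$median),
            .data$barrier_id)
}

#' Write a rank-summary table to CSV
#'
#' @param summaries Output of [summarize_ranks()] or [summarize_all_ranks()].
#' @param path Output path.
#' @return `summaries`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  readr::write_csv(summaries, path, progress = FALSE)
  invisible(summaries)
}
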