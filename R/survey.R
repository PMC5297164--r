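# Survey datasets: respondents plus their rank-order ballots.
#
# Ballots are stored exactly as elicited ("raw" direction): for influence a
# higher raw rank means LOWER influence, for difficulty a higher raw rank
# means LEAST difficult. Conversion to the canonical reporting direction
# happens downstream (see canonicalize_rank()), never at parse time, so the
# raw data stay auditable.

#' Read a respondent table
#'
#' Requires columns `respondent_id` and `group` (a professional-group code:
#' EN, EDr, SN, SDr, SP or BM); any further columns are kept as demographics.
#'
#' @param path Path to a comma- or tab-delimited file.
#' @return A tibble of respondents.
#' @examples
#' read_respondents(paretorank_example("stroke_respondents_synthetic.csv"))
#' @export
read_respondents <- function(path) {
  resp <- read_delim_auto(path)
  validate_respondents(resp)
}

validate_respondents <- function(resp) {
  resp <- as_tibble(resp)
  missing_cols <- setdiff(c("respondent_id", "group"), names(resp))
  if (length(missing_cols)) {
    abort(sprintf("respondent table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  dup <- resp$respondent_id[duplicated(resp$respondent_id)]
  if (length(dup)) {
    abort(sprintf("duplicate respondent_id: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  unknown <- setdiff(unique(resp$group), GROUP_CODES)
  if (length(unknown)) {
    abort(sprintf("unknown professional-group code(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  resp
}

#' Assemble and validate a survey dataset
#'
#' Enforces the elicitation contract: every ballot is a complete, tie-free
#' ranking (a bijection onto `1..n_barriers`) of one behaviour's barriers by
#' one respondent for one attribute, stored in the raw elicitation direction;
#' each respondent contributes at most one ballot per (behaviour, attribute);
#' and respondents only rank behaviours their professional group is eligible
#' for. Whole ballots may be absent (a respondent may skip an eligible
#' behaviour); partial ballots may not.
#'
#' @param catalogue A [barrier_catalogue()].
#' @param respondents Respondent data frame (see [read_respondents()]).
#' @param ballots Long-format ballot data frame: one row per
#'   (respondent, behaviour, attribute, barrier) with columns `respondent_id`,
#'   `behaviour_id`, `attribute` (`"influence"` or `"difficulty"`),
#'   `barrier_id`, `rank`.
#' @param on_ineligible What to do with a ballot from a respondent whose group
#'   is not eligible for the behaviour: `"error"` (default) or `"drop"`
#'   (drop with a warning).
#' @return An object of class `survey_dataset`: list with elements
#'   `catalogue`, `respondents`, `ballots`.
#' @export
survey_dataset <- function(catalogue, respondents, ballots,
                           on_ineligible = c("error", "drop")) {
  stopifnot(inherits(catalogue, "barrier_catalogue"))
  on_ineligible <- match.arg(on_ineligible)
  respondents <- validate_respondents(respondents)
  ballots <- as_tibble(ballots)

  required <- c("respondent_id", "behaviour_id", "attribute", "barrier_id", "rank")
  missing_cols <- setdiff(required, names(ballots))
  if (length(missing_cols)) {
    abort(sprintf("ballot table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  ballots$behaviour_id <- as.character(ballots$behaviour_id)
  ballots$barrier_id <- as.character(ballots$barrier_id)
  ballots$rank <- as.integer(ballots$rank)

  bad_attr <- setdiff(unique(ballots$attribute), ATTRIBUTES)
  if (length(bad_attr)) {
    abort(sprintf("unknown attribute(s): %s (expected influence/difficulty)",
                  paste(bad_attr, collapse = ", ")))
  }
  unknown_resp <- setdiff(unique(ballots$respondent_id), respondents$respondent_id)
  if (length(unknown_resp)) {
    abort(sprintf("ballots from unknown respondent(s): %s",
                  paste(unknown_resp, collapse = ", ")))
  }
  unknown_beh <- setdiff(unique(ballots$behaviour_id),
                         catalogue$behaviours$behaviour_id)
  if (length(unknown_beh)) {
    abort(sprintf("ballots for unknown behaviour(s): %s",
                  paste(unknown_beh, collapse = ", ")))
  }
  # barrier belongs to its behaviour
  key <- paste(ballots$behaviour_id, ballots$barrier_id)
  ok_key <- paste(catalogue$barriers$behaviour_id, catalogue$barriers$barrier_id)
  if (any(!key %in% ok_key)) {
    bad <- unique(ballots$barrier_id[!key %in% ok_key])
    abort(sprintf("ballot rows reference barrier(s) outside their behaviour: %s",
                  paste(bad, collapse = ", ")))
  }

  # eligibility
  grp <- respondents$group[match(ballots$respondent_id, respondents$respondent_id)]
  elig <- vapply(seq_len(nrow(ballots)), function(i) {
    grp[i] %in% eligible_groups_of(catalogue, ballots$behaviour_id[i])
  }, logical(1))
  if (any(!elig)) {
    offenders <- unique(paste0(ballots$respondent_id[!elig], " (", grp[!elig],
                               ") on behaviour ", ballots$behaviour_id[!elig]))
    msg <- sprintf("ballot(s) from ineligible professional group: %s",
                   paste(offenders, collapse = "; "))
    if (on_ineligible == "error") abort(msg)
    warn(paste0(msg, " - dropped"))
    ballots <- ballots[elig, , drop = FALSE]
  }

  # bijection per (respondent, behaviour, attribute): no ties, no gaps,
  # every barrier of the behaviour ranked exactly once
  check <- ballots |>
    group_by(.data$respondent_id, .data$behaviour_id, .data$attribute) |>
    summarise(
      complete = identical(sort(.data$rank),
                           seq_len(n_barriers(catalogue, .data$behaviour_id[1]))) &&
        setequal(.data$barrier_id,
                 behaviour_barriers(catalogue, .data$behaviour_id[1])) &&
        !anyDuplicated(.data$barrier_id),
      .groups = "drop"
    )
  if (any(!check$complete)) {
    bad <- check[!check$complete, ]
    abort(sprintf(
      "invalid ballot (tie, gap, or incomplete ranking): %s",
      paste(sprintf("%s / behaviour %s / %s", bad$respondent_id,
                    bad$behaviour_id, bad$attribute), collapse = "; ")))
  }

  structure(
    list(catalogue = catalogue, respondents = respondents, ballots = ballots),
    class = "survey_dataset"
  )
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf(
    "<survey_dataset> %d respondents, %d ballots over %d behaviours\n",
    nrow(x$respondents),
    nrow(distinct(x$ballots, .data$respondent_id, .data$behaviour_id,
                  .data$attribute)),
    length(unique(x$ballots$behaviour_id))))
  invisible(x)
}

#' Read a survey dataset (ballots + respondents) from delimited files
#'
#' @param catalogue A [barrier_catalogue()] the ballots refer to.
#' @param ballots_path Path to the long-format ballot file (columns
#'   `respondent_id`, `behaviour_id`, `attribute`, `barrier_id`, `rank`).
#' @param respondents_path Path to the respondent file.
#' @inheritParams survey_dataset
#' @return A [survey_dataset()].
#' @export
read_survey <- function(catalogue, ballots_path, respondents_path,
                        on_ineligible = c("error", "drop")) {
  respondents <- read_respondents(respondents_path)
  ballots <- read_delim_auto(ballots_path)
  ballots$rank <- as.integer(ballots$rank)
  survey_dataset(catalogue, respondents, ballots,
                 on_ineligible = match.arg(on_ineligible))
}

#' Write a survey dataset back to delimited files
#'
#' Writes the ballots (and optionally the respondents) as CSV; a dataset
#' written and re-read with [read_survey()] reproduces itself record for
#' record.
#'
#' @param dataset A [survey_dataset()].
#' @param ballots_path Output path for the ballot file.
#' @param respondents_path Optional output path for the respondent file.
#' @return `dataset`, invisibly.
#' @export
write_survey <- function(dataset, ballots_path, respondents_path = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  readr::write_csv(dataset$ballots, ballots_path, progress = FALSE)
  if (!is.null(respondents_path)) {
    readr::write_csv(dataset$respondents, respondents_path, progress = FALSE)
  }
  invisible(dataset)
}

#' Tabulate a demographic field as counts and percentages
#'
#' Percentages are `100 * count / n`, reported to one decimal place; counts
#' always sum to the number of respondents.
#'
#' @param respondents Respondent data frame.
#' @param field Name of the demographic column to tabulate.
#' @return A tibble with columns `category`, `n`, `pct`, in order of first
#'   appearance.
#' @examples
#' resp <- read_respondents(paretorank_example("stroke_respondents_synthetic.csv"))
#' demographic_percentages(resp, "sex")
#' @export
demographic_percentages <- function(respondents, field) {
  respondents <- as_tibble(respondents)
  if (nrow(respondents) == 0) {
    abort("cannot tabulate demographics of an empty respondent table")
  }
  if (!field %in% names(respondents)) {
    abort(sprintf("no such demographic field: %s", field))
  }
  values <- respondents[[field]]
  if (anyNA(values)) {
    abort(sprintf("field '%s' has missing values", field))
  }
  categories <- unique(values)
  counts <- vapply(categories, function(v) sum(values == v), integer(1),
                   USE.NAMES = FALSE)
  tibble(
    category = as.character(categories),
    n = counts,
    pct = round(100 * counts / length(values), 1)
  )
}
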