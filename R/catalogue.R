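# Behaviour/barrier catalogue: the data model behind every other module.
# A catalogue lists the targeted clinical behaviours, each with an ordered set
# of candidate barriers and the professional groups eligible to rank them.
# The ranking scale for both attributes is always 1..n_barriers.

#' Construct a behaviour/barrier catalogue
#'
#' A catalogue holds the targeted behaviours, each with its ordered list of
#' barriers and the professional groups whose members are eligible to submit
#' ballots for it. The ranking scale for each behaviour (both attributes) is
#' `1..n_barriers` by construction.
#'
#' @param barriers A data frame with one row per barrier and columns
#'   `behaviour_id`, `behaviour_name`, `barrier_id`, `barrier_description`,
#'   `eligible_groups` (group codes separated by `;`). Barrier order within a
#'   behaviour is taken as the catalogue order.
#' @return An object of class `barrier_catalogue`: a list with tibbles
#'   `behaviours` (`behaviour_id`, `behaviour_name`, `n_barriers`,
#'   `eligible_groups` list-column) and `barriers` (`barrier_id`,
#'   `behaviour_id`, `description`).
#' @seealso [read_catalogue()] to load one from a delimited file.
#' @export
barrier_catalogue <- function(barriers) {
  required <- c("behaviour_id", "behaviour_name", "barrier_id",
                "barrier_description", "eligible_groups")
  missing_cols <- setdiff(required, names(barriers))
  if (length(missing_cols)) {
    abort(sprintf("catalogue is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  barriers <- as_tibble(barriers)
  barriers$behaviour_id <- as.character(barriers$behaviour_id)
  barriers$barrier_id <- as.character(barriers$barrier_id)

  dup <- barriers$barrier_id[duplicated(barriers$barrier_id)]
  if (length(dup)) {
    abort(sprintf("duplicate barrier_id in catalogue: %s",
                  paste(unique(dup), collapse = ", ")))
  }

  behaviours <- barriers |>
    group_by(.data$behaviour_id) |>
    summarise(
      behaviour_name = .data$behaviour_name[1],
      n_barriers = n(),
      eligible_groups = list(parse_groups(.data$eligible_groups[1])),
      .groups = "drop"
    ) |>
    arrange(match(.data$behaviour_id, unique(barriers$behaviour_id)))

  # one consistent name and eligibility per behaviour
  inconsistent <- barriers |>
    group_by(.data$behaviour_id) |>
    summarise(ok = length(unique(.data$behaviour_name)) == 1 &&
                length(unique(.data$eligible_groups)) == 1,
              .groups = "drop")
  if (any(!inconsistent$ok)) {
    abort(sprintf(
      "behaviour(s) with inconsistent name or eligible_groups across rows: %s",
      paste(inconsistent$behaviour_id[!inconsistent$ok], collapse = ", ")))
  }
  if (any(behaviours$n_barriers < 2)) {
    abort(sprintf("behaviour(s) with fewer than 2 barriers: %s",
                  paste(behaviours$behaviour_id[behaviours$n_barriers < 2],
                        collapse = ", ")))
  }
  for (i in seq_len(nrow(behaviours))) {
    unknown <- setdiff(behaviours$eligible_groups[[i]], GROUP_CODES)
    if (length(unknown)) {
      abort(sprintf("behaviour %s: unknown professional-group code(s): %s",
                    behaviours$behaviour_id[i], paste(unknown, collapse = ", ")))
    }
  }

  structure(
    list(
      behaviours = behaviours,
      barriers = barriers |>
        select(barrier_id = "barrier_id", behaviour_id = "behaviour_id",
               description = "barrier_description")
    ),
    class = "barrier_catalogue"
  )
}

parse_groups <- function(x) {
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Read a behaviour/barrier catalogue from a delimited file
#'
#' The file must have columns `behaviour_id`, `behaviour_name`, `barrier_id`,
#' `barrier_description` and `eligible_groups` (professional-group codes
#' separated by `;`). Comma or tab delimiters are auto-detected from the
#' header line.
#'
#' @param path Path to the catalogue file.
#' @return A [barrier_catalogue()] object.
#' @examples
#' cat9 <- read_catalogue(paretorank_example("stroke_catalogue.csv"))
#' cat9
#' @export
read_catalogue <- function(path) {
  barrier_catalogue(read_delim_auto(path))
}

# Delimiter autodetection (tab wins if present in the header line), with
# parse problems surfaced as errors naming the offending line.
read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  out <- suppressWarnings(  # parse problems are re-raised as errors below
    readr::read_delim(path, delim = delim, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE, show_col_types = FALSE))
  probs <- readr::problems(out)
  if (nrow(probs)) {
    abort(sprintf("parse error in %s at line %d: expected %s, got %s",
                  path, probs$row[1], probs$expected[1], probs$actual[1]))
  }
  out
}

#' @export
print.barrier_catalogue <- function(x, ...) {
  cat(sprintf("<barrier_catalogue> %d behaviours, %d barriers\n",
              nrow(x$behaviours), nrow(x$barriers)))
  for (i in seq_len(nrow(x$behaviours))) {
    cat(sprintf("  %s %s (%d barriers; groups: %s)\n",
                x$behaviours$behaviour_id[i], x$behaviours$behaviour_name[i],
                x$behaviours$n_barriers[i],
                paste(x$behaviours$eligible_groups[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Barriers of one behaviour, in catalogue order
#'
#' @param catalogue A [barrier_catalogue()].
#' @param behaviour_id Behaviour identifier.
#' @return Character vector of barrier ids.
#' @export
behaviour_barriers <- function(catalogue, behaviour_id) {
  stopifnot(inherits(catalogue, "barrier_catalogue"))
  if (!behaviour_id %in% catalogue$behaviours$behaviour_id) {
    abort(sprintf("unknown behaviour_id: %s", behaviour_id))
  }
  catalogue$barriers$barrier_id[catalogue$barriers$behaviour_id == behaviour_id]
}

#' Number of barriers (equals the ranking-scale maximum) for a behaviour
#'
#' @inheritParams behaviour_barriers
#' @return Integer.
#' @export
n_barriers <- function(catalogue, behaviour_id) {
  length(behaviour_barriers(catalogue, behaviour_id))
}

eligible_groups_of <- function(catalogue, behaviour_id) {
  b <- catalogue$behaviours
  b$eligible_groups[[match(behaviour_id, b$behaviour_id)]]
}
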