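# Synthetic expert panels: Mallows-model ballots around per-attribute
# ground-truth orders, with discipline-specific ballot completion mirroring
# the elicitation design (each group ranks only its eligible behaviours).

#' Panel simulation configuration
#'
#' @param catalogue A [barrier_catalogue()].
#' @param dispersion Non-negative Mallows concentration: ballot probability is
#'   proportional to `exp(-dispersion * kendall_tau_distance_to_truth)`.
#'   `0` gives uniformly random ballots; large values make every ballot equal
#'   the truth. Default 2, a moderately concordant panel.
#' @param panel Named integer vector of panel composition (respondents per
#'   professional-group code). Default mirrors the surveyed panel: 3 EN,
#'   3 EDr, 3 SN, 3 SDr, 3 SP, 2 BM (17 respondents).
#' @param truth Ground-truth orders: named list
#'   `truth[[behaviour_id]][[attribute]]`, each a permutation of the
#'   behaviour's barriers, best first (most influential / least difficult
#'   first). Defaults to the catalogue barrier order for both attributes.
#' @param seed Optional integer seed; when set, [simulate_panel()] is
#'   reproducible and leaves the global RNG state untouched.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(catalogue,
                         dispersion = 2,
                         panel = c(EN = 3, EDr = 3, SN = 3, SDr = 3, SP = 3, BM = 2),
                         truth = NULL,
                         seed = NULL) {
  stopifnot(inherits(catalogue, "barrier_catalogue"))
  if (!is.numeric(dispersion) || length(dispersion) != 1 || dispersion < 0) {
    abort("dispersion must be a single non-negative number")
  }
  panel <- panel[panel > 0]
  unknown <- setdiff(names(panel), GROUP_CODES)
  if (length(unknown)) {
    abort(sprintf("unknown professional-group code(s) in panel: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (!length(panel) || sum(panel) == 0) {
    abort("panel must contain at least one respondent")
  }
  if (is.null(truth)) {
    truth <- lapply(catalogue$behaviours$behaviour_id, function(bid) {
      ord <- behaviour_barriers(catalogue, bid)
      list(influence = ord, difficulty = ord)
    })
    names(truth) <- catalogue$behaviours$behaviour_id
  }
  for (bid in catalogue$behaviours$behaviour_id) {
    for (attr in ATTRIBUTES) {
      if (!setequal(truth[[bid]][[attr]], behaviour_barriers(catalogue, bid))) {
        abort(sprintf("truth for behaviour %s / %s is not a permutation of its barriers",
                      bid, attr))
      }
    }
  }
  structure(
    list(catalogue = catalogue, dispersion = dispersion,
         panel = panel, truth = truth, seed = seed),
    class = "panel_config"
  )
}

#' Read a panel simulation configuration from YAML
#'
#' Recognised fields: `dispersion`, `seed`, `panel` (map of group code to
#' count), and optionally `truth` (map behaviour id -> attribute -> barrier
#' list, best first).
#'
#' @param path Path to the YAML file.
#' @param catalogue A [barrier_catalogue()].
#' @return A [panel_config()].
#' @export
read_panel_config <- function(path, catalogue) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  panel_config(
    catalogue,
    dispersion = cfg$dispersion %||% 2,
    panel = unlist(cfg$panel %||%
                     c(EN = 3, EDr = 3, SN = 3, SDr = 3, SP = 3, BM = 2)),
    truth = cfg$truth,
    seed = cfg$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw one ranking from a Mallows model by repeated insertion
#'
#' Samples a permutation with probability proportional to
#' `exp(-dispersion * d)` where `d` is the Kendall-tau distance to
#' `reference`. Uses the repeated-insertion method, which is exact: item `j`
#' of the reference is inserted at position `i` of the partial order with
#' probability proportional to `exp(-dispersion)^(j - i)`. Dispersion 0 gives
#' the uniform distribution over permutations; dispersion -> Inf concentrates
#' on the reference itself.
#'
#' @param reference Character vector, the central order (best first).
#' @param dispersion Non-negative concentration parameter.
#' @return A permutation of `reference`, best first.
#' @export
sample_mallows <- function(reference, dispersion) {
  if (!is.numeric(dispersion) || length(dispersion) != 1 || dispersion < 0) {
    abort("dispersion must be a single non-negative number")
  }
  n <- length(reference)
  if (n <= 1) return(reference)
  phi <- exp(-dispersion)
  ord <- reference[1]
  for (j in 2:n) {
    w <- phi^((j - 1):0)  # positions 1..j; inserting at i adds j - i inversions
    pos <- sample.int(j, 1L, prob = w)
    ord <- append(ord, reference[j], after = pos - 1L)
  }
  ord
}

#' Simulate a full survey dataset from a panel configuration
#'
#' Generates one ballot per eligible (respondent, behaviour, attribute): a
#' Mallows draw around the behaviour/attribute truth, emitted in the raw
#' elicitation direction (influence: raw rank 1 = most influential;
#' difficulty: raw rank 1 = most difficult). Behaviours with no eligible
#' respondent in the panel are skipped with a warning. With a `seed` in the
#' config the result is reproducible.
#'
#' @param config A [panel_config()].
#' @return A [survey_dataset()].
#' @examples
#' cat9 <- read_catalogue(paretorank_example("stroke_catalogue.csv"))
#' sim <- simulate_panel(panel_config(cat9, dispersion = 5, seed = 1))
#' sim
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  if (!is.null(config$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old_seed)) {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(config$seed)
  }

  catalogue <- config$catalogue
  respondents <- bind_rows(lapply(names(config$panel), function(g) {
    tibble(respondent_id = sprintf("%s%d", g, seq_len(config$panel[[g]])),
           group = g)
  }))

  pieces <- list()
  for (bid in catalogue$behaviours$behaviour_id) {
    eligible <- respondents$respondent_id[
      respondents$group %in% eligible_groups_of(catalogue, bid)]
    if (!length(eligible)) {
      warn(sprintf("behaviour %s has no eligible respondents in the panel; skipped",
                   bid))
      next
    }
    nb <- n_barriers(catalogue, bid)
    for (rid in eligible) {
      for (attr in ATTRIBUTES) {
        ord <- sample_mallows(config$truth[[bid]][[attr]], config$dispersion)
        # position k (best) -> canonical rank nb + 1 - k -> raw direction
        pos <- seq_len(nb)  # position of each barrier in the drawn order
        raw <- if (attr == "influence") pos else nb + 1L - pos
        pieces[[length(pieces) + 1L]] <- tibble(
          respondent_id = rid, behaviour_id = bid, attribute = attr,
          barrier_id = ord, rank = raw
        )
      }
    }
  }
  if (!length(pieces)) abort("no behaviour has eligible respondents")
  survey_dataset(catalogue, respondents, bind_rows(pieces))
}
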