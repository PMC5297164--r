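# End-to-end pipeline: inputs -> summaries -> group rankings ->
# classification -> plots, with a run log. The command-line interface in
# inst/cli/paretorank.R is a thin wrapper over these functions.

#' Run the full prioritisation pipeline
#'
#' Either aggregates raw ballots (`ballots` + `respondents`) into group
#' rankings with the chosen voting rule, or starts from precomputed group
#' ranks (`group_ranks`) when raw ballots are unavailable. Then classifies
#' every behaviour's barriers by desirability and writes all artefacts to
#' `outdir`: `summaries.csv` (ballot mode only), `group_ranks.csv`,
#' `desirability.csv`, one `behaviour_<id>.<format>` plot per behaviour, and
#' `run_log.txt`. Inputs are read and validated before anything is written,
#' so a failing run leaves no partial output.
#'
#' @param catalogue Path to a catalogue file, or a [barrier_catalogue()].
#' @param ballots,respondents Paths (or data frames) for ballot mode.
#' @param group_ranks Path (or wide tibble) for precomputed-group-ranks mode.
#' @param method Voting rule for ballot mode (see
#'   [aggregate.pairwise_matrix()]).
#' @param outdir Output directory (created if needed).
#' @param plot_format `"png"`, `"svg"` or `"pdf"`.
#' @return List with `summaries`, `group_ranks`, `results`,
#'   `desirability`, `files`, invisibly.
#' @export
run_pipeline <- function(catalogue, ballots = NULL, respondents = NULL,
                         group_ranks = NULL, method = "schulze",
                         outdir, plot_format = "png") {
  catalogue <- as_catalogue(catalogue)
  if (is.null(group_ranks) && is.null(ballots)) {
    abort("supply either ballots + respondents or group_ranks")
  }

  summaries <- NULL
  if (!is.null(ballots)) {
    dataset <- if (inherits(ballots, "survey_dataset")) {
      ballots
    } else {
      read_survey(catalogue, ballots, respondents)
    }
    summaries <- summarize_all_ranks(dataset)
    gr <- aggregate_dataset(dataset, method = method)
  } else {
    gr <- if (is.data.frame(group_ranks)) {
      group_ranks
    } else {
      read_group_ranks(catalogue, group_ranks)
    }
    method <- "precomputed"
  }

  results <- classify_dataset(gr[, c("behaviour_id", "barrier_id",
                                     "influence_rank", "difficulty_rank")])
  tab <- desirability_table(results)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (!is.null(summaries)) {
    f <- file.path(outdir, "summaries.csv")
    write_summaries(summaries, f)
    files <- c(files, f)
  }
  f <- file.path(outdir, "group_ranks.csv")
  write_group_ranks(gr, f)
  files <- c(files, f)
  f <- file.path(outdir, "desirability.csv")
  write_desirability(tab, f)
  files <- c(files, f)
  for (bid in names(results)) {
    f <- file.path(outdir, sprintf("behaviour_%s.%s", bid, plot_format))
    nm <- catalogue$behaviours$behaviour_name[
      match(bid, catalogue$behaviours$behaviour_id)]
    plot_behaviour(results[[bid]], out = f, title = nm)
    files <- c(files, f)
  }
  log_file <- file.path(outdir, "run_log.txt")
  writeLines(c(
    sprintf("paretorank %s", as.character(utils::packageVersion("paretorank"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("R version: %s", R.version.string),
    sprintf("mode: %s", if (method == "precomputed") "group-ranks" else "ballots"),
    sprintf("method: %s", method),
    sprintf("behaviours: %d", length(results)),
    sprintf("barriers: %d", nrow(tab))
  ), log_file)
  files <- c(files, log_file)

  invisible(list(summaries = summaries, group_ranks = gr, results = results,
                 desirability = tab, files = files))
}

as_catalogue <- function(x) {
  if (inherits(x, "barrier_catalogue")) x else read_catalogue(x)
}

#' Simulate a panel and write the survey files
#'
#' @param config A [panel_config()] or a path to a YAML config (requires
#'   `catalogue`).
#' @param outdir Output directory; receives `ballots.csv`, `respondents.csv`
#'   and `sim_log.txt`.
#' @param catalogue Catalogue (path or object), needed when `config` is a
#'   path.
#' @return The simulated [survey_dataset()], invisibly.
#' @export
simulate_to_dir <- function(config, outdir, catalogue = NULL) {
  if (is.character(config)) {
    if (is.null(catalogue)) abort("a catalogue is required with a config file")
    config <- read_panel_config(config, as_catalogue(catalogue))
  }
  dataset <- simulate_panel(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_survey(dataset,
               ballots_path = file.path(outdir, "ballots.csv"),
               respondents_path = file.path(outdir, "respondents.csv"))
  writeLines(c(
    sprintf("paretorank %s", as.character(utils::packageVersion("paretorank"))),
    sprintf("dispersion: %g", config$dispersion),
    sprintf("seed: %s", config$seed %||% "none"),
    sprintf("panel: %s",
            paste(sprintf("%s=%d", names(config$panel), config$panel),
                  collapse = ", "))
  ), file.path(outdir, "sim_log.txt"))
  invisible(dataset)
}
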