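# Quadrant scatter plots: influence (right = more influential) vs difficulty
# (up = less difficult). The most desirable barrier to target sits in the top
# right corner.

#' Plot coordinates for one behaviour's classification
#'
#' Exposes the exact coordinates a [plot_behaviour()] figure will use, so the
#' geometry is testable without rendering. Exactly coincident points (group
#' ranks tied on both attributes) are offset by a small deterministic jitter
#' (a hash of the barrier id mapped to an angle, radius 0.1 rank units —
#' always below 0.15) and flagged as tied.
#'
#' @param result A `desirability_result` from [classify_barriers()].
#' @return Tibble with columns `barrier_id`, `influence_rank`,
#'   `difficulty_rank`, `x`, `y`, `desirability`, `tied`.
#' @export
behaviour_plot_data <- function(result) {
  stopifnot(inherits(result, "desirability_result"))
  pts <- result$labels
  key <- paste(pts$influence_rank, pts$difficulty_rank)
  tied <- key %in% key[duplicated(key)]
  offset <- vapply(pts$barrier_id, barrier_jitter_angle, numeric(1))
  tibble(
    barrier_id = pts$barrier_id,
    influence_rank = pts$influence_rank,
    difficulty_rank = pts$difficulty_rank,
    x = pts$influence_rank + ifelse(tied, 0.1 * cos(offset), 0),
    y = pts$difficulty_rank + ifelse(tied, 0.1 * sin(offset), 0),
    desirability = pts$desirability,
    tied = tied
  )
}

# Deterministic angle in [0, 2*pi) from the barrier id text, so re-rendering
# a figure never moves a point.
barrier_jitter_angle <- function(id) {
  codes <- utf8ToInt(id)
  h <- sum(codes * seq_along(codes) * 31) %% 97
  2 * pi * h / 97
}

#' Quadrant scatter plot of one behaviour's barriers
#'
#' Horizontal axis: group influence rank (higher = more influential, to the
#' right). Vertical axis: group difficulty rank (higher = less difficult,
#' up). Points are labelled with their barrier id, coloured and shaped by
#' desirability; exact ties are jittered deterministically and marked with a
#' trailing `*`. Axis limits are fixed to `[0.5, n_barriers + 0.5]` so plots
#' are comparable across behaviours.
#'
#' @param result A `desirability_result` from [classify_barriers()].
#' @param out Optional output path; the extension selects the device
#'   (`.png`, `.svg` or `.pdf`).
#' @param title Optional plot title (e.g. the behaviour name).
#' @return The ggplot object, invisibly.
#' @export
plot_behaviour <- function(result, out = NULL, title = NULL) {
  dat <- behaviour_plot_data(result)
  nb <- nrow(dat)
  dat$label_text <- paste0(dat$barrier_id, ifelse(dat$tied, "*", ""))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$desirability,
                                         shape = .data$desirability)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label_text),
                       vjust = -0.9, size = 3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(most_desirable = "#1b9e77",
                                            desirable = "#7570b3",
                                            least_desirable = "#969696"),
                                 drop = FALSE) +
    ggplot2::scale_shape_manual(values = c(most_desirable = 17,
                                           desirable = 16,
                                           least_desirable = 15),
                                drop = FALSE) +
    ggplot2::scale_x_continuous(limits = c(0.5, nb + 0.5),
                                breaks = seq_len(nb)) +
    ggplot2::scale_y_continuous(limits = c(0.5, nb + 0.5),
                                breaks = seq_len(nb)) +
    ggplot2::labs(
      x = "Group rank, influence (higher = more influential)",
      y = "Group rank, difficulty (higher = less difficult)",
      colour = "Desirability", shape = "Desirability",
      title = title %||% sprintf("Behaviour %s", result$behaviour_id),
      caption = if (any(dat$tied)) "* tied group ranks (jittered)" else NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(out)) {
    save_plot_file(p, out)
  }
  invisible(p)
}

save_plot_file <- function(p, out, width = 5.5, height = 5) {
  ext <- tolower(tools::file_ext(out))
  opened <- switch(ext,
    png = grDevices::png(out, width = width, height = height, units = "in",
                         res = 150),
    svg = grDevices::svg(out, width = width, height = height),
    pdf = grDevices::pdf(out, width = width, height = height),
    abort(sprintf("unsupported plot format: .%s (use png, svg or pdf)", ext))
  )
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(out)
}
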