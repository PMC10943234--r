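#' Plot a similarity trace
#'
#' Scores against session time, optionally shading detected freezing bouts.
#'
#' @param object A [similarity_trace()].
#' @param bouts Optional `bout_table` to shade.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.similarity_trace <- function(object, bouts = NULL, ...) {
  fps <- trace_fps(object)
  d <- dplyr::mutate(as_tibble(object), time_s = (.data$index - 1) / fps)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$score))
  if (!is.null(bouts) && nrow(bouts) > 0) {
    shade <- dplyr::mutate(as_tibble(bouts),
                           xmin = (.data$start_index - 1) / fps,
                           xmax = .data$end_index / fps)
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.25)
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = expression(r^2 ~ "similarity score"),
                  title = trace_source_id(object)) +
    ggplot2::theme_minimal()
}

#' Plot a mixture fit over the score histogram
#'
#' @param object A `freeze_gmm`.
#' @param trace The trace the model was fit to.
#' @param bins Histogram bin count (default 120).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.freeze_gmm <- function(object, trace, bins = 120, ...) {
  x <- trace_scores(trace)
  comp <- object$components
  grid <- seq(min(x), max(x), length.out = 512)
  dens <- purrr::pmap_dfr(comp, function(component, weight, mean, sd) {
    tibble(component = component, score = grid,
           density = weight * dnorm(grid, mean, sd))
  })
  ggplot2::ggplot(tibble(score = x), ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", color = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density, color = .data$component),
                       linewidth = 0.8) +
    ggplot2::labs(x = expression(r^2 ~ "similarity score"), y = "Density",
                  color = "Component", title = object$source_id) +
    ggplot2::theme_minimal()
}

#' Plot a posterior trace
#'
#' Freezing and motion membership probabilities along the session.
#'
#' @param object A [posterior_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.posterior_trace <- function(object, ...) {
  fps <- attr(object, "fps") %||% 30
  d <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(object), time_s = (.data$index - 1) / fps),
    cols = c("p_motion", "p_ambiguous", "p_freezing"),
    names_to = "component", values_to = "posterior")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$posterior,
                                  color = .data$component)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Posterior probability") +
    ggplot2::theme_minimal()
}

#' Plot per-minute freezing probabilities for a cohort
#'
#' Thin per-subject lines with the grand mean overlaid.
#'
#' @param bin_matrix Subjects x bins matrix (e.g. `freeze_cohort$bin_matrix`).
#' @return A ggplot.
#' @export
plot_minute_bins <- function(bin_matrix) {
  d <- as_tibble(as.data.frame(bin_matrix), rownames = "source_id") |>
    tidyr::pivot_longer(-"source_id", names_to = "bin", values_to = "prob") |>
    dplyr::mutate(bin = as.integer(factor(.data$bin, levels = unique(.data$bin))))
  gm <- dplyr::summarise(dplyr::group_by(d, .data$bin),
                         prob = mean(.data$prob), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$prob)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$source_id),
                       alpha = 0.3, linewidth = 0.3) +
    ggplot2::geom_line(data = gm, color = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "Minute bin", y = "P(freezing)") +
    ggplot2::theme_minimal()
}
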