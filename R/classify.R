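#' Bout-detection configuration
#'
#' Parameters that turn posterior probabilities into freezing bouts. Freezing
#' is operationally defined as 3 or more seconds (90 frames at 30 fps) of no
#' movement, so runs of qualifying frame-pairs shorter than `min_bout_frames`
#' are never classified as freezing.
#'
#' A frame-pair qualifies when its posterior probability of membership in the
#' freezing component is at least `posterior_threshold` *and* its similarity
#' score is not an anomaly with respect to the freezing component under a
#' Tukey quartile fence: the component's quartiles `Q1`/`Q3` are taken at
#' `1 - freezing_quantile` and `freezing_quantile` of its Gaussian, and scores
#' below `Q1 - tukey_k * (Q3 - Q1)` are rejected however high their posterior.
#' The default multiplier is Tukey's "far out" value 3; the conventional 1.5
#' fence marks about 0.35% of clean Gaussian scores as anomalous, and because
#' a bout requires 90 consecutive qualifying frames, even that small rate
#' shatters genuine bouts (see the methods vignette). Setting
#' `strict_quantile_cut = TRUE` instead requires the score to lie at or above
#' `Q3` itself — i.e. inside the rightmost 25% of the freezing density — a
#' much stricter variant that flags at most the top quartile of genuinely
#' frozen frames and is provided for sensitivity analyses rather than as the
#' default.
#'
#' @param min_bout_frames Minimum run length, in frame-pairs, of a freezing
#'   bout (default 90, i.e. 3 s at 30 fps).
#' @param posterior_threshold Minimum freezing-component posterior
#'   (default 0.95).
#' @param freezing_quantile Upper-quartile level anchoring the Tukey cut
#'   (default 0.75).
#' @param tukey_k Fence multiplier (default 3, Tukey's far-out fence; 1.5
#'   gives the conventional stricter fence).
#' @param strict_quantile_cut Require scores at or above the freezing
#'   component's `freezing_quantile` quantile (default `FALSE`).
#' @return A list of class `bout_config`.
#' @export
bout_config <- function(min_bout_frames = 90, posterior_threshold = 0.95,
                        freezing_quantile = 0.75, tukey_k = 3,
                        strict_quantile_cut = FALSE) {
  if (min_bout_frames < 1) {
    abort("`min_bout_frames` must be at least 1.", class = "stillframe_config_error")
  }
  if (posterior_threshold <= 0 || posterior_threshold >= 1 ||
      freezing_quantile <= 0 || freezing_quantile >= 1) {
    abort("Thresholds must lie in (0, 1).", class = "stillframe_config_error")
  }
  structure(list(min_bout_frames = as.integer(min_bout_frames),
                 posterior_threshold = posterior_threshold,
                 freezing_quantile = freezing_quantile, tukey_k = tukey_k,
                 strict_quantile_cut = isTRUE(strict_quantile_cut)),
            class = "bout_config")
}

#' Flag qualifying (freezing-candidate) frame-pairs
#'
#' Applies the posterior threshold and the Tukey quartile rule of
#' [bout_config()] to every score.
#'
#' @param post A [posterior_trace()].
#' @param model The `freeze_gmm` the posteriors came from.
#' @param trace The [similarity_trace()] scored (defaults to the scores
#'   carried by `post`).
#' @param cfg A [bout_config()].
#' @return Logical vector, one flag per score.
#' @export
qualifying_frames <- function(post, model, trace = NULL, cfg = bout_config()) {
  scores <- if (is.null(trace)) post$score else trace_scores(trace)
  if (length(scores) != nrow(post)) {
    abort("Trace and posterior lengths differ.", class = "stillframe_input_error")
  }
  f <- model$components[model$components$component == "freezing", ]
  z <- qnorm(cfg$freezing_quantile)
  q3 <- f$mean + z * f$sd
  q1 <- f$mean - z * f$sd
  cut <- if (cfg$strict_quantile_cut) q3 else q1 - cfg$tukey_k * (q3 - q1)
  post$p_freezing >= cfg$posterior_threshold & scores >= cut
}

#' Detect freezing bouts from qualifying-frame flags
#'
#' Each maximal run of `TRUE` flags at least `min_bout_frames` long becomes
#' one bout; shorter stillness is not freezing, and runs separated by any
#' movement are separate bouts (4 s of freezing, movement, then 10 s of
#' freezing is two bouts of 4 s and 10 s).
#'
#' @param flags Logical vector from [qualifying_frames()].
#' @param fps Frames per second.
#' @param cfg A [bout_config()].
#' @param source_id Session identifier carried on the table.
#' @return A tibble of class `bout_table` with columns `bout`, `start_index`,
#'   `end_index` (inclusive score indices), `start_s`, `duration_s`.
#' @export
detect_bouts <- function(flags, fps = 30, cfg = bout_config(),
                         source_id = "session") {
  stopifnot(fps > 0)
  flags <- as.logical(flags)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= cfg$min_bout_frames
  out <- tibble(bout = seq_len(sum(keep)),
                start_index = starts[keep], end_index = ends[keep]) |>
    dplyr::mutate(start_s = (.data$start_index - 1L) / fps,
                  duration_s = (.data$end_index - .data$start_index + 1L) / fps)
  attr(out, "fps") <- fps
  attr(out, "n_scores") <- length(flags)
  attr(out, "source_id") <- source_id
  class(out) <- c("bout_table", class(out))
  out
}

#' Motor activity of a session
#'
#' The summed posterior probability of motion-component membership over all
#' scores: an objective, unitless index of how much the animal moved, bounded
#' by `[0, length(trace)]`.
#'
#' @param post A [posterior_trace()].
#' @return A single number.
#' @export
motor_activity <- function(post) sum(post$p_motion)

#' Summarize a session
#'
#' Aggregates a bout table and posterior trace into the per-subject measures
#' used in downstream analyses: total freezing duration, number of freezing
#' episodes, mean episode duration, motor activity, and the fraction of the
#' session spent inside freezing bouts.
#'
#' @param bouts A `bout_table` from [detect_bouts()].
#' @param post The session's [posterior_trace()].
#' @return A one-row tibble: `source_id`, `total_freezing_s`, `n_bouts`,
#'   `mean_bout_s` (0 when there are no bouts), `motor_activity`,
#'   `freezing_fraction`.
#' @export
summarize_session <- function(bouts, post) {
  n_scores <- attr(bouts, "n_scores") %||% nrow(post)
  if (nrow(bouts) > 0) {
    if (any(bouts$end_index < bouts$start_index) ||
        any(bouts$start_index[-1] <= bouts$end_index[-nrow(bouts)]) ||
        bouts$end_index[nrow(bouts)] > n_scores) {
      abort("Bouts must be disjoint, ordered and within the trace.",
            class = "stillframe_internal_error")
    }
  }
  total <- sum(bouts$duration_s)
  n <- nrow(bouts)
  tibble(source_id = attr(bouts, "source_id") %||% "session",
         total_freezing_s = total,
         n_bouts = n,
         mean_bout_s = if (n > 0) total / n else 0,
         motor_activity = motor_activity(post),
         freezing_fraction = sum(bouts$end_index - bouts$start_index + 1L) /
           n_scores)
}

#' Per-score freezing membership implied by a bout table
#'
#' @param bouts A `bout_table`.
#' @param n_scores Trace length (defaults to the length recorded on the
#'   table).
#' @return Logical vector: `TRUE` where the score lies inside a bout.
#' @export
bout_membership <- function(bouts, n_scores = NULL) {
  n_scores <- n_scores %||% attr(bouts, "n_scores")
  inside <- logical(n_scores)
  for (i in seq_len(nrow(bouts))) {
    inside[bouts$start_index[i]:bouts$end_index[i]] <- TRUE
  }
  inside
}
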