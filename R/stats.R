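#' Split-half freezing comparison
#'
#' Compares per-subject total freezing between the first and second halves of
#' the session with an independent-samples, equal-variance t test (so a
#' cohort of 18 subjects yields 34 degrees of freedom). Bouts straddling the
#' session midpoint contribute to each half in proportion to their overlap.
#' Used to test for habituation across the session.
#'
#' @param bouts_by_subject Named list of `bout_table`s, one per subject.
#' @param session_s Session length in seconds (must be the same for all
#'   subjects; halves split it evenly).
#' @return A one-row tibble: `statistic` (t), `df`, `p.value`,
#'   `mean_first_s`, `mean_second_s`, `n_subjects`.
#' @export
split_half_test <- function(bouts_by_subject, session_s) {
  if (length(bouts_by_subject) < 2) {
    abort("Need at least 2 subjects.", class = "stillframe_input_error")
  }
  halves <- purrr::map(bouts_by_subject, function(b) {
    fps <- attr(b, "fps") %||% 30
    mid <- session_s / 2
    start_s <- (b$start_index - 1) / fps
    end_s <- b$end_index / fps
    first <- sum(pmax(0, pmin(end_s, mid) - start_s))
    second <- sum(pmax(0, end_s - pmax(start_s, mid)))
    c(first = first, second = second)
  })
  first <- purrr::map_dbl(halves, "first")
  second <- purrr::map_dbl(halves, "second")
  if (sd(first) == 0 && sd(second) == 0) {
    if (all(first == second)) {
      # identical halves: no evidence of change
      return(tibble(statistic = 0, df = 2 * length(first) - 2, p.value = 1,
                    mean_first_s = mean(first), mean_second_s = mean(second),
                    n_subjects = length(first)))
    }
    abort("Zero variance in both halves; t statistic undefined.",
          class = "stillframe_undefined_statistic_error")
  }
  tt <- t.test(first, second, var.equal = TRUE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value, mean_first_s = mean(first),
         mean_second_s = mean(second), n_subjects = length(first))
}

#' Per-minute freezing probabilities
#'
#' Partitions a session into consecutive bins (default 60 s) and reports, for
#' each bin, the fraction of its similarity scores that lie inside a freezing
#' bout.
#'
#' @param bouts A `bout_table`.
#' @param n_scores Trace length in scores (defaults to the length recorded on
#'   the table).
#' @param fps Frames per second.
#' @param bin_length_s Bin length in seconds (default 60).
#' @return A tibble: `bin`, `n_scores`, `n_freezing`, `prob`.
#' @export
minute_bins <- function(bouts, n_scores = NULL, fps = NULL, bin_length_s = 60) {
  n_scores <- n_scores %||% attr(bouts, "n_scores")
  fps <- fps %||% attr(bouts, "fps") %||% 30
  if (is.null(n_scores)) {
    abort("Trace length unknown; pass `n_scores`.", class = "stillframe_input_error")
  }
  per_bin <- as.integer(round(bin_length_s * fps))
  if (n_scores < per_bin) {
    abort("Session shorter than one bin.", class = "stillframe_input_error")
  }
  inside <- bout_membership(bouts, n_scores)
  bin_of <- pmin(((seq_len(n_scores) - 1L) %/% per_bin) + 1L,
                 ceiling(n_scores / per_bin))
  tibble(bin = seq_len(max(bin_of)),
         n_scores = tabulate(bin_of),
         n_freezing = as.integer(tapply(inside, bin_of, sum))) |>
    dplyr::mutate(prob = .data$n_freezing / .data$n_scores)
}

#' Linear trend in grand-mean per-bin freezing
#'
#' Averages per-bin freezing probabilities across subjects and reports the
#' Pearson correlation of the grand mean against bin index (1..K) — a test
#' for a monotone drift (habituation or sensitization) over the session.
#'
#' @param bin_matrix Numeric matrix, subjects x bins, of per-bin freezing
#'   probabilities (e.g. rows of [minute_bins()]`$prob`).
#' @return A one-row tibble: `estimate` (r), `p.value`, `n_bins`, and
#'   `constant_series` (`TRUE`, with `NA` statistics, when the grand mean
#'   does not vary and the trend is undefined).
#' @export
grand_mean_trend <- function(bin_matrix) {
  bin_matrix <- as.matrix(bin_matrix)
  gm <- colMeans(bin_matrix)
  k <- length(gm)
  if (k < 3 || sd(gm) == 0) {
    # constant grand mean (or too few bins): the trend is undefined
    return(tibble(estimate = NA_real_, p.value = NA_real_, n_bins = k,
                  constant_series = k >= 3 && sd(gm) == 0))
  }
  ct <- cor.test(gm, seq_len(k))
  tibble(estimate = unname(ct$estimate), p.value = ct$p.value, n_bins = k,
         constant_series = FALSE)
}

#' Correlate two subject-level measures
#'
#' Pearson correlation between two columns of a subject table, with the
#' option to log-transform the outcome first — freezing durations are
#' right-skewed, so analyses use `ln(y + 1)` (the +1 offset accommodates
#' subjects that never froze). The 95% confidence interval comes from the
#' Fisher z transform.
#'
#' @param table Data frame with one row per subject.
#' @param x,y Column names (strings).
#' @param log_transform_y Apply `ln(y + 1)` to `y` before correlating.
#' @return A one-row tibble: `estimate` (r), `p.value`, `conf.low`,
#'   `conf.high`, `n`, `x`, `y`, `log_transform_y`.
#' @export
correlate <- function(table, x, y, log_transform_y = FALSE) {
  xv <- as.numeric(table[[x]])
  yv <- as.numeric(table[[y]])
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (length(xv) < 3) {
    abort("Need at least 3 complete pairs.", class = "stillframe_input_error")
  }
  if (log_transform_y) yv <- log1p(yv)
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("Correlation undefined for a constant column.",
          class = "stillframe_undefined_correlation_error")
  }
  ct <- cor.test(xv, yv)
  tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
         conf.low = ct$conf.int[1], conf.high = ct$conf.int[2],
         n = length(xv), x = x, y = y, log_transform_y = log_transform_y)
}
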