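#' Denoising configuration
#'
#' Parameters of the two-step trace denoiser: outlier substitution followed by
#' median filtering. Dropped video frames and lighting aliasing produce
#' isolated, implausibly low similarity scores in otherwise smooth fixed-camera
#' recordings; both steps exist to remove those artifacts while leaving the
#' behavioral signal intact.
#'
#' @param outlier_threshold Scores at or below this value are treated as
#'   artifacts and replaced by the modal score (default 0.93). In practice all
#'   genuine behavior in fixed-camera cage video — including locomotion — keeps
#'   consecutive-frame similarity above this level; only frame drops and
#'   aliasing fall below it.
#' @param median_kernel Odd window length, in frames, of the median filter
#'   (default 3, the recommended setting).
#' @param mode_bin_width Histogram bin width used to define the modal score of
#'   a continuous trace (default 0.001 similarity units).
#' @return A list of class `denoise_config`.
#' @export
denoise_config <- function(outlier_threshold = 0.93, median_kernel = 3,
                           mode_bin_width = 0.001) {
  if (!is.numeric(outlier_threshold) || outlier_threshold <= 0 ||
      outlier_threshold >= 1) {
    abort("`outlier_threshold` must be in (0, 1).", class = "stillframe_config_error")
  }
  median_kernel <- as.integer(median_kernel)
  if (is.na(median_kernel) || median_kernel < 1 || median_kernel %% 2 == 0) {
    abort("`median_kernel` must be an odd positive integer.",
          class = "stillframe_config_error")
  }
  if (!is.numeric(mode_bin_width) || mode_bin_width <= 0 || mode_bin_width >= 1) {
    abort("`mode_bin_width` must be in (0, 1).", class = "stillframe_config_error")
  }
  structure(list(outlier_threshold = outlier_threshold,
                 median_kernel = median_kernel,
                 mode_bin_width = mode_bin_width),
            class = "denoise_config")
}

#' Modal similarity score
#'
#' The mode of a continuous-valued trace is defined as the center of the most
#' populated histogram bin (bins of width `mode_bin_width` spanning `[0, 1]`),
#' computed over non-outlier scores only — substituting outliers with a value
#' that is itself estimated from outliers would be self-defeating. Ties are
#' broken toward the higher bin.
#'
#' @param scores Numeric vector of similarity scores.
#' @param cfg A [denoise_config()].
#' @return The modal score (a bin center).
#' @export
#' @examples
#' modal_score(c(0.99, 0.99, 0.99, 0.50)) # 0.9905
modal_score <- function(scores, cfg = denoise_config()) {
  scores <- trace_scores(scores)
  keep <- scores > cfg$outlier_threshold
  if (!any(keep)) {
    abort(paste0("All scores are at or below the outlier threshold; the trace ",
                 "is degenerate and needs manual handling."),
          class = "stillframe_degenerate_trace_error")
  }
  w <- cfg$mode_bin_width
  nbins <- ceiling(1 / w)
  idx <- pmin(floor(scores[keep] / w), nbins - 1)
  counts <- tabulate(idx + 1L, nbins = nbins)
  best <- max(which(counts == max(counts)))   # tie -> higher bin
  (best - 1L + 0.5) * w
}

#' Substitute outlier scores with the modal score
#'
#' Every score at or below `outlier_threshold` is replaced by
#' [modal_score()] of the trace; all other scores pass through unchanged.
#'
#' @inheritParams modal_score
#' @return Numeric vector of the same length.
#' @export
substitute_outliers <- function(scores, cfg = denoise_config()) {
  scores <- trace_scores(scores)
  out <- scores <= cfg$outlier_threshold
  if (!any(out)) return(scores)
  scores[out] <- modal_score(scores, cfg)
  scores
}

#' Sliding-window median filter
#'
#' Median filter with symmetric-reflect padding at both ends (the boundary
#' sample is mirrored, so a kernel-3 window at index 1 sees
#' `x[1], x[1], x[2]`). Kernel 1 is the identity.
#'
#' @inheritParams modal_score
#' @return Numeric vector of the same length.
#' @export
median_filter <- function(scores, cfg = denoise_config()) {
  x <- trace_scores(scores)
  k <- cfg$median_kernel
  if (k == 1) return(x)
  n <- length(x)
  if (k > n) {
    abort("Median kernel exceeds trace length.", class = "stillframe_config_error")
  }
  h <- (k - 1L) %/% 2L
  padded <- c(x[h:1], x, x[n:(n - h + 1L)])
  filt <- stats::runmed(padded, k, endrule = "keep")
  filt[(h + 1L):(h + n)]
}

#' Denoise a similarity trace
#'
#' Applies the two denoising steps in order — outlier substitution, then
#' median filtering — and returns a trace flagged as denoised. This is the
#' vector handed to the mixture model.
#'
#' @param trace A [similarity_trace()] (or bare numeric vector).
#' @param cfg A [denoise_config()].
#' @return A [similarity_trace()] of identical length.
#' @export
denoise <- function(trace, cfg = denoise_config()) {
  scores <- median_filter(substitute_outliers(trace, cfg), cfg)
  similarity_trace(scores,
                   fps = if (is.data.frame(trace)) trace_fps(trace) else 30,
                   source_id = if (is.data.frame(trace)) trace_source_id(trace) else "session",
                   denoised = TRUE)
}
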