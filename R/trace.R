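#' Similarity traces
#'
#' A similarity trace is the central signal of the pipeline: one squared
#' Pearson correlation (r-squared, a *similarity score*) per pair of
#' consecutive grayscale video frames, ordered in video time. High scores mean
#' the scene barely changed between frames (the animal is still); low scores
#' mean motion. `similarity_trace()` builds the container from a numeric
#' vector; [compute_similarity_trace()] builds it from frames.
#'
#' The trace is a tibble with columns `index` (1-based score index; score `i`
#' spans the transition between frames `i` and `i + 1`) and `score`, carrying
#' `fps` and `source_id` as attributes. All durations downstream are computed
#' as score counts divided by `fps`.
#'
#' @param scores Numeric vector of similarity scores, each in `[0, 1]`.
#' @param fps Frames per second of the source video (default 30).
#' @param source_id Subject/session identifier string.
#' @param denoised Logical flag recording whether the trace has been denoised.
#'
#' @return A tibble of class `similarity_trace` with columns `index`, `score`.
#' @seealso [compute_similarity_trace()], [denoise()], [fit_mixture()]
#' @export
#' @examples
#' tr <- similarity_trace(c(0.99, 0.98, 0.99), fps = 30, source_id = "demo")
#' trace_fps(tr)
similarity_trace <- function(scores, fps = 30, source_id = "session",
                             denoised = FALSE) {
  scores <- as.numeric(scores)
  if (length(scores) < 1) {
    abort("A similarity trace needs at least one score.", class = "stillframe_input_error")
  }
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    abort("Similarity scores must be finite and in [0, 1].",
          class = "stillframe_input_error")
  }
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0) {
    abort("`fps` must be a single positive number.", class = "stillframe_input_error")
  }
  out <- tibble(index = seq_along(scores), score = scores)
  attr(out, "fps") <- as.numeric(fps)
  attr(out, "source_id") <- as.character(source_id)
  attr(out, "denoised") <- isTRUE(denoised)
  class(out) <- c("similarity_trace", class(out))
  out
}

#' @rdname similarity_trace
#' @param trace A `similarity_trace`.
#' @export
trace_fps <- function(trace) attr(trace, "fps") %||% 30

#' @rdname similarity_trace
#' @export
trace_source_id <- function(trace) attr(trace, "source_id") %||% "session"

#' @rdname similarity_trace
#' @export
trace_scores <- function(trace) {
  if (inherits(trace, "similarity_trace") || is.data.frame(trace)) {
    as.numeric(trace$score)
  } else {
    as.numeric(trace)
  }
}

#' Similarity between two grayscale frames
#'
#' Computes the squared Pearson correlation between the flattened pixel
#' vectors of two frames of identical dimensions. Identical (non-constant)
#' frames score 1; independent noise scores near 0.
#'
#' Degenerate variance is handled explicitly: if both frames are constant and
#' pixelwise equal the score is 1 (nothing changed); if either frame is
#' constant and the frames differ anywhere, the score is 0, treating the
#' transition as a large change so that the denoiser's outlier rule catches it
#' (constant frames arise from dropped or blanked video frames, not from a
#' live scene).
#'
#' @param frame_a,frame_b Numeric matrices of identical dimensions with at
#'   least 2 pixels; intensities on any common scale.
#' @return A single similarity score in `[0, 1]`.
#' @export
#' @examples
#' a <- matrix(runif(64), 8, 8)
#' frame_similarity(a, a) # 1
frame_similarity <- function(frame_a, frame_b) {
  if (!identical(dim(frame_a), dim(frame_b))) {
    abort("Frames must have identical dimensions.", class = "stillframe_input_error")
  }
  a <- as.numeric(frame_a)
  b <- as.numeric(frame_b)
  if (length(a) < 2) {
    abort("Frames must contain at least 2 pixels.", class = "stillframe_input_error")
  }
  const_a <- all(a == a[1])
  const_b <- all(b == b[1])
  if (const_a || const_b) {
    return(if (all(a == b)) 1 else 0)
  }
  r <- cor(a, b)
  min(1, r^2)
}

#' Frame sequences
#'
#' A frame sequence holds ordered 2-D grayscale frames from one fixed-camera
#' session, either supplied directly or read by [read_video()]. Frames are
#' stored as a list of numeric matrices sharing one size.
#'
#' @param frames List of numeric matrices with identical dimensions (at least
#'   2 frames).
#' @param fps Frames per second (default 30).
#' @param source_id Subject/session identifier.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps = 30, source_id = "session") {
  if (!is.list(frames) || length(frames) < 2) {
    abort("A frame sequence needs at least 2 frames.", class = "stillframe_input_error")
  }
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d), logical(1))
  if (!all(ok)) {
    abort("All frames must be matrices sharing identical dimensions.",
          class = "stillframe_input_error")
  }
  structure(
    list(frames = frames, fps = as.numeric(fps),
         width = d[2], height = d[1], source_id = as.character(source_id)),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %s: %d frames, %dx%d px, %.6g fps\n",
              x$source_id, length(x$frames), x$width, x$height, x$fps))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Compute the similarity trace of a frame sequence
#'
#' Scores every pair of consecutive frames with [frame_similarity()]; the
#' resulting trace has one score fewer than the sequence has frames.
#'
#' @param seq A [frame_sequence()].
#' @return A [similarity_trace()] with `length(seq) - 1` scores.
#' @export
compute_similarity_trace <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  n <- length(seq$frames)
  # vectorized over frames: per-frame sums / consecutive cross-products
  X <- vapply(seq$frames, as.numeric, numeric(seq$width * seq$height))
  npx <- nrow(X)
  s1 <- colSums(X)
  s2 <- colSums(X^2)
  cross <- colSums(X[, -n, drop = FALSE] * X[, -1, drop = FALSE])
  va <- s2 - s1^2 / npx
  cov_ab <- cross - s1[-n] * s1[-1] / npx
  scores <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    if (va[i] <= 0 || va[i + 1] <= 0) {
      scores[i] <- if (isTRUE(all.equal(X[, i], X[, i + 1], tolerance = 0)) ||
                       all(X[, i] == X[, i + 1])) 1 else 0
    } else {
      r2 <- cov_ab[i]^2 / (va[i] * va[i + 1])
      scores[i] <- min(1, max(0, r2))
    }
  }
  similarity_trace(scores, fps = seq$fps, source_id = seq$source_id)
}
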