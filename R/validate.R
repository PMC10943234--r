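#' Sample validation segments from a scored session
#'
#' Draws fixed-length segments for human rating: `n_per_class` lying entirely
#' inside detected freezing bouts and `n_per_class` entirely outside them,
#' mutually non-overlapping, sampled uniformly at random under a fixed seed.
#' These are the clips raters score blind as freezing / non-freezing.
#'
#' @param bouts A `bout_table`.
#' @param n_scores Trace length (defaults to the length on the table).
#' @param fps Frames per second.
#' @param n_per_class Segments per class (default 10, giving a 50/50 set).
#' @param segment_s Segment length in seconds (default 3).
#' @param seed Integer seed.
#' @return A tibble: `segment_id`, `class` (`"freezing"`/`"non-freezing"`),
#'   `start_index`, `end_index`.
#' @export
sample_segments <- function(bouts, n_scores = NULL, fps = NULL,
                            n_per_class = 10, segment_s = 3, seed = 1) {
  n_scores <- n_scores %||% attr(bouts, "n_scores")
  fps <- fps %||% attr(bouts, "fps") %||% 30
  seg <- as.integer(round(segment_s * fps))
  inside <- bout_membership(bouts, n_scores)
  # candidate starts whose whole segment stays in one class
  runs_for <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= seg
    unlist(purrr::map2(starts[keep], ends[keep],
                       function(s, e) s:(e - seg + 1L)), use.names = FALSE)
  }
  with_local_seed(seed, {
    pick <- function(cands, n, label) {
      chosen <- integer(0)
      cands <- as.integer(cands)
      while (length(chosen) < n) {
        if (length(cands) == 0) {
          abort(sprintf("Not enough disjoint %s material to sample %d segments.",
                        label, n),
                class = "stillframe_sampling_error")
        }
        s <- cands[sample.int(length(cands), 1)]
        chosen <- c(chosen, s)
        cands <- cands[cands > s + seg - 1L | cands < s - seg + 1L]
      }
      sort(chosen)
    }
    fz <- pick(runs_for(inside), n_per_class, "freezing")
    nf <- pick(runs_for(!inside), n_per_class, "non-freezing")
    tibble(segment_id = seq_len(2 * n_per_class),
           class = rep(c("freezing", "non-freezing"), each = n_per_class),
           start_index = c(fz, nf)) |>
      dplyr::mutate(end_index = .data$start_index + seg - 1L)
  })
}

#' Consensus of rater labels
#'
#' Per-segment majority (modal) label across raters; exact ties are coded as
#' non-freezing — the conservative direction, matching the convention that a
#' segment is only a "true" freezing outcome when most raters call it one.
#'
#' @param labels Matrix or data frame, segments x raters, of binary labels
#'   (1 = freezing).
#' @return Integer vector of consensus labels.
#' @export
consensus <- function(labels) {
  m <- as.matrix(labels)
  if (ncol(m) < 2) {
    abort("Consensus needs at least 2 raters.", class = "stillframe_input_error")
  }
  as.integer(rowMeans(m) > 0.5)
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with observed
#' agreement `p_o` and chance agreement `p_e` from the two raters' marginal
#' label frequencies. When `p_e = 1` (both raters constant and identical) the
#' statistic is defined as 1 if agreement is perfect, otherwise an error.
#'
#' @param a,b Binary vectors of equal length.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(a, b) {
  a <- as.integer(a)
  b <- as.integer(b)
  if (length(a) != length(b) || length(a) < 1) {
    abort("Label vectors must have equal positive length.",
          class = "stillframe_input_error")
  }
  po <- mean(a == b)
  pa1 <- mean(a == 1)
  pb1 <- mean(b == 1)
  pe <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  if (abs(1 - pe) < .Machine$double.eps) {
    if (po == 1) return(1)
    abort("Chance agreement is 1 but observed agreement is not; kappa undefined.",
          class = "stillframe_undefined_metric_error")
  }
  (po - pe) / (1 - pe)
}

#' Permutation p value for an observed kappa
#'
#' One-sided p value for agreement above chance, obtained by shuffling the
#' second label vector `n_perm` times under a fixed seed and counting
#' permuted kappas at least as large as the observed one (add-one estimator).
#'
#' @inheritParams cohen_kappa
#' @param n_perm Number of permutations (default 1999).
#' @param seed Integer seed.
#' @return A list with `kappa` and `p.value`.
#' @export
kappa_permutation_test <- function(a, b, n_perm = 1999, seed = 1) {
  obs <- cohen_kappa(a, b)
  perm <- with_local_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) cohen_kappa(a, sample(b)), numeric(1))
  })
  list(kappa = obs, p.value = (1 + sum(perm >= obs)) / (n_perm + 1))
}

#' Sensitivity and specificity against a reference
#'
#' @param pred Binary predictions (1 = freezing).
#' @param truth Binary reference labels containing both classes.
#' @return A list with `sensitivity` (`TP / (TP + FN)`) and `specificity`
#'   (`TN / (TN + FP)`).
#' @export
sensitivity_specificity <- function(pred, truth) {
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (length(pred) != length(truth)) {
    abort("Vectors must have equal length.", class = "stillframe_input_error")
  }
  if (length(unique(truth)) < 2) {
    abort("Reference labels contain a single class; metrics undefined.",
          class = "stillframe_undefined_metric_error")
  }
  list(sensitivity = sum(pred == 1 & truth == 1) / sum(truth == 1),
       specificity = sum(pred == 0 & truth == 0) / sum(truth == 0))
}

#' Round-robin interrater reliability
#'
#' Unweighted mean of Cohen's kappa over all unordered rater pairs — the
#' human-vs-human agreement benchmark the classifier is compared against.
#'
#' @param labels Matrix or data frame, segments x raters, of binary labels.
#' @return Mean pairwise kappa.
#' @export
round_robin <- function(labels) {
  m <- as.matrix(labels)
  if (ncol(m) < 2) {
    abort("Round-robin IRR needs at least 2 raters.",
          class = "stillframe_input_error")
  }
  pairs <- utils::combn(ncol(m), 2)
  mean(apply(pairs, 2, function(p) cohen_kappa(m[, p[1]], m[, p[2]])))
}

#' Full rater-validation report
#'
#' Computes, from a set of rater labels and the classifier's per-segment
#' labels: every pairwise human kappa and their mean (round-robin IRR), the
#' classifier's kappa against each rater and against the rater consensus, and
#' sensitivity/specificity taking the consensus as the true outcome.
#'
#' @param rater_labels Matrix or data frame, segments x raters, binary.
#' @param classifier_labels Binary vector of the classifier's segment labels.
#' @return A list of class `validation_report`: `pairwise_kappas` (tibble),
#'   `mean_pairwise_kappa`, `kappa_vs_raters` (tibble), `kappa_vs_consensus`,
#'   `sensitivity`, `specificity`, `consensus`, `n_segments`, `tie_segments`
#'   (count of exact rater ties coded non-freezing).
#' @export
validation_report <- function(rater_labels, classifier_labels) {
  m <- as.matrix(rater_labels)
  cls <- as.integer(classifier_labels)
  if (nrow(m) != length(cls)) {
    abort("Classifier labels must cover every segment.",
          class = "stillframe_input_error")
  }
  cons <- consensus(m)
  pairs <- utils::combn(ncol(m), 2)
  pk <- tibble(
    rater_a = colnames(m)[pairs[1, ]] %||% paste0("R", pairs[1, ]),
    rater_b = colnames(m)[pairs[2, ]] %||% paste0("R", pairs[2, ]),
    kappa = apply(pairs, 2, function(p) cohen_kappa(m[, p[1]], m[, p[2]])))
  vs <- tibble(
    rater = colnames(m) %||% paste0("R", seq_len(ncol(m))),
    kappa = apply(m, 2, function(col) cohen_kappa(cls, col)))
  ss <- sensitivity_specificity(cls, cons)
  structure(list(
    pairwise_kappas = pk,
    mean_pairwise_kappa = mean(pk$kappa),
    kappa_vs_raters = vs,
    kappa_vs_consensus = cohen_kappa(cls, cons),
    sensitivity = ss$sensitivity, specificity = ss$specificity,
    consensus = cons, n_segments = nrow(m),
    tie_segments = sum(rowMeans(m) == 0.5)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d segments\n", x$n_segments))
  cat(sprintf("  mean human-vs-human kappa (round-robin): %.3f\n",
              x$mean_pairwise_kappa))
  cat(sprintf("  classifier vs consensus kappa: %.3f\n", x$kappa_vs_consensus))
  cat(sprintf("  sensitivity %.3f, specificity %.3f\n",
              x$sensitivity, x$specificity))
  if (x$tie_segments > 0) {
    cat(sprintf("  %d tied segments coded non-freezing\n", x$tie_segments))
  }
  invisible(x)
}

#' Read rater labels from long-format CSV
#'
#' Expects columns `segment_id`, `rater_id`, `label` (0/1) with every rater
#' labeling every segment.
#'
#' @param path CSV path.
#' @return Matrix, segments x raters.
#' @export
read_rater_labels <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  wide <- tidyr::pivot_wider(d, id_cols = "segment_id",
                             names_from = "rater_id", values_from = "label")
  wide <- dplyr::arrange(wide, .data$segment_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(m)) {
    abort("Every rater must label every segment.", class = "stillframe_input_error")
  }
  rownames(m) <- wide$segment_id
  m
}
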