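#' Mixture-model configuration
#'
#' Controls the per-subject one-dimensional Gaussian mixture fit. The method
#' fixes three components — freezing (highest similarity), ambiguous (middle)
#' and motion (lowest) — and stabilizes the fit by running many independent
#' EM restarts from randomized initializations, keeping the solution with the
#' highest log-likelihood.
#'
#' @param n_components Number of mixture components; the published method
#'   fixes 3 and other values are refused.
#' @param n_restarts Independent EM restarts (default 300).
#' @param seed Integer seed for the restart initializations.
#' @param min_component_weight Winning-fit components below this mixing
#'   proportion trigger the edge-case flag (default 0.01).
#' @param min_mean_separation Minimum separation, in similarity units, between
#'   adjacent component means before the edge-case flag is raised
#'   (default 0.005).
#' @param max_em_iters Maximum EM iterations per restart (default 500).
#' @param em_tol Absolute log-likelihood change declaring convergence
#'   (default 1e-8).
#' @return A list of class `mixture_config`.
#' @export
mixture_config <- function(n_components = 3, n_restarts = 300, seed = 1,
                           min_component_weight = 0.01,
                           min_mean_separation = 0.005,
                           max_em_iters = 500, em_tol = 1e-8) {
  if (n_components != 3) {
    abort("The method fixes 3 mixture components (freezing/ambiguous/motion).",
          class = "stillframe_config_error")
  }
  if (n_restarts < 1) {
    abort("`n_restarts` must be at least 1.", class = "stillframe_config_error")
  }
  structure(list(n_components = 3L, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed),
                 min_component_weight = min_component_weight,
                 min_mean_separation = min_mean_separation,
                 max_em_iters = as.integer(max_em_iters), em_tol = em_tol),
            class = "mixture_config")
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

component_labels <- c("motion", "ambiguous", "freezing")

new_freeze_gmm <- function(weight, mean, sd, log_likelihood = NA_real_,
                           converged = NA, n_iter = NA_integer_,
                           manual_override = FALSE, restart_logliks = NULL,
                           seed = NA_integer_, n = NA_integer_,
                           trace_sd = NA_real_, source_id = "session",
                           min_component_weight = 0.01,
                           min_mean_separation = 0.005) {
  ord <- order(mean)
  comp <- tibble(component = component_labels,
                 weight = weight[ord], mean = mean[ord], sd = sd[ord])
  reasons <- character()
  if (any(comp$weight < min_component_weight)) {
    reasons <- c(reasons, "component weight below minimum")
  }
  if (any(diff(comp$mean) < min_mean_separation)) {
    reasons <- c(reasons, "component means insufficiently separated")
  }
  structure(
    list(components = comp, log_likelihood = log_likelihood,
         converged = converged, n_iter = n_iter,
         manual_override = manual_override,
         edge_case = length(reasons) > 0, edge_case_reasons = reasons,
         restart_logliks = restart_logliks, seed = seed, n = n,
         trace_sd = trace_sd, source_id = source_id),
    class = "freeze_gmm"
  )
}

#' Fit the per-subject similarity-score mixture
#'
#' Fits a three-component 1-D Gaussian mixture to a denoised similarity trace
#' by expectation-maximization, restarted `n_restarts` times from randomized
#' initializations (means drawn at the trace's 10th/50th/90th percentiles and
#' jittered with seeded noise; common initial sd; uniform weights). The
#' restart with the highest final log-likelihood wins. Components are labeled
#' by ascending mean: lowest = motion (large frame-to-frame change), middle =
#' ambiguous, highest = freezing.
#'
#' Sessions in which the animal almost never or almost always moves cannot
#' support three distinct components; such fits carry an edge-case flag
#' (tiny component weight or collapsed means) and should be reviewed and, if
#' needed, replaced via [override_components()] — the semi-automated contract.
#'
#' @param trace A denoised [similarity_trace()] (or numeric vector) with at
#'   least `30 * n_components` scores.
#' @param cfg A [mixture_config()].
#' @return An object of class `freeze_gmm`; see [tidy.freeze_gmm()] and
#'   [glance.freeze_gmm()].
#' @export
fit_mixture <- function(trace, cfg = mixture_config()) {
  x <- trace_scores(trace)
  src <- if (is.data.frame(trace)) trace_source_id(trace) else "session"
  if (length(x) < 30 * cfg$n_components) {
    abort(sprintf("Need at least %d scores to fit the mixture.",
                  30 * cfg$n_components),
          class = "stillframe_input_error")
  }
  if (all(x == x[1])) {
    abort(paste0("All similarity scores are identical; the mixture is ",
                 "degenerate. Review the session and set component point ",
                 "estimates manually with override_components()."),
          class = "stillframe_degeneracy_error")
  }
  s <- sd(x)
  anchors <- quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
  mu0 <- with_local_seed(cfg$seed, {
    jitter <- matrix(rnorm(cfg$n_restarts * 3, sd = s), ncol = 3)
    sweep(jitter, 2, anchors, `+`)
  })
  fit <- .em_restarts(x, mu0, sigma0 = max(s, 1e-4),
                      max_iter = cfg$max_em_iters, tol = cfg$em_tol,
                      var_floor = 1e-8)
  new_freeze_gmm(weight = fit$weight, mean = fit$mean, sd = fit$sd,
                 log_likelihood = fit$log_likelihood,
                 converged = fit$converged, n_iter = fit$n_iter,
                 restart_logliks = fit$restart_logliks,
                 seed = cfg$seed, n = length(x), trace_sd = s,
                 source_id = src,
                 min_component_weight = cfg$min_component_weight,
                 min_mean_separation = cfg$min_mean_separation)
}

#' Manually override mixture point estimates
#'
#' Implements the manual arm of the semi-automated protocol: a reviewer who
#' has watched the video sets the component means directly (e.g. for an
#' animal that never moved, so that every frame classifies as freezing
#' downstream). Omitted standard deviations and weights keep the fitted
#' values when `model` carries a fit; when building a model from scratch
#' (`model = NULL`), they default to the pooled trace standard deviation and
#' uniform weights, for which `trace` must be supplied.
#'
#' @param model A `freeze_gmm` fit, or `NULL` to build a manual model.
#' @param means Three similarity values in `[0, 1]`, distinct after sorting.
#' @param sds Optional three positive standard deviations.
#' @param weights Optional three mixing proportions summing to 1.
#' @param trace Trace used for the pooled-sd default when `model` is `NULL`.
#' @return A `freeze_gmm` with `manual_override = TRUE` and labels reassigned
#'   by ascending mean.
#' @export
override_components <- function(model = NULL, means, sds = NULL, weights = NULL,
                                trace = NULL) {
  means <- as.numeric(means)
  if (length(means) != 3 || anyNA(means) || !all(is.finite(means)) ||
      any(means < 0 | means > 1)) {
    abort("`means` must be three finite values in [0, 1].",
          class = "stillframe_input_error")
  }
  if (anyDuplicated(means)) {
    abort("`means` must be distinct (strictly increasing after sorting).",
          class = "stillframe_input_error")
  }
  if (is.null(sds)) {
    sds <- if (!is.null(model)) {
      model$components$sd
    } else {
      if (is.null(trace)) {
        abort("Supply `trace` (for pooled-sd defaults) when `model` is NULL.",
              class = "stillframe_input_error")
      }
      rep(max(sd(trace_scores(trace)), 1e-4), 3)
    }
  }
  if (any(sds <= 0)) {
    abort("`sds` must be positive.", class = "stillframe_input_error")
  }
  if (is.null(weights)) {
    weights <- if (!is.null(model)) model$components$weight else rep(1 / 3, 3)
  }
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    abort("`weights` must be non-negative and sum to 1.",
          class = "stillframe_input_error")
  }
  # align omitted sds/weights with the sorted order of the new means
  ord <- order(means)
  new_freeze_gmm(weight = weights, mean = means[ord], sd = sds,
                 log_likelihood = if (!is.null(model)) model$log_likelihood else NA_real_,
                 converged = if (!is.null(model)) model$converged else NA,
                 manual_override = TRUE,
                 seed = if (!is.null(model)) model$seed else NA_integer_,
                 n = if (!is.null(model)) model$n else NA_integer_,
                 trace_sd = if (!is.null(model)) model$trace_sd else NA_real_,
                 source_id = if (!is.null(model)) model$source_id else "session")
}

#' Posterior component membership along a trace
#'
#' For every similarity score, computes the posterior probability of
#' membership in each labeled component,
#' `P(k | s) = w_k N(s; mu_k, sd_k) / sum_j w_j N(s; mu_j, sd_j)`,
#' evaluated in log space so extreme scores never produce NaN. The result
#' recapitulates the video timecourse as per-frame-pair probabilities of
#' motion, ambiguity and freezing.
#'
#' @param model A `freeze_gmm`.
#' @param trace A [similarity_trace()] (or numeric vector).
#' @return A tibble of class `posterior_trace` with columns `index`, `score`,
#'   `p_motion`, `p_ambiguous`, `p_freezing`; rows sum to 1.
#' @export
posterior_trace <- function(model, trace) {
  stopifnot(inherits(model, "freeze_gmm"))
  x <- trace_scores(trace)
  comp <- model$components
  logd <- vapply(seq_len(3), function(k) {
    log(max(comp$weight[k], 1e-300)) +
      dnorm(x, comp$mean[k], comp$sd[k], log = TRUE)
  }, numeric(length(x)))
  logd <- matrix(logd, ncol = 3)
  m <- apply(logd, 1, max)
  p <- exp(logd - m)
  p <- p / rowSums(p)
  out <- tibble(index = seq_along(x), score = x,
                p_motion = p[, comp$component == "motion"],
                p_ambiguous = p[, comp$component == "ambiguous"],
                p_freezing = p[, comp$component == "freezing"])
  attr(out, "fps") <- if (is.data.frame(trace)) trace_fps(trace) else 30
  attr(out, "source_id") <- if (is.data.frame(trace)) trace_source_id(trace) else
    model$source_id
  class(out) <- c("posterior_trace", class(out))
  out
}

#' @export
print.freeze_gmm <- function(x, ...) {
  cat(sprintf("<freeze_gmm> %s (n = %s%s%s)\n", x$source_id,
              x$n, if (isTRUE(x$manual_override)) ", manual override" else "",
              if (isTRUE(x$edge_case)) ", EDGE CASE - review required" else ""))
  print(x$components)
  if (is.finite(x$log_likelihood)) {
    cat(sprintf("log-likelihood %.4f; converged: %s\n",
                x$log_likelihood, x$converged))
  }
  invisible(x)
}

#' Tidy a mixture fit
#'
#' @param x A `freeze_gmm`.
#' @param ... Unused.
#' @return One row per component: `component`, `weight`, `mean`, `sd`.
#' @export
tidy.freeze_gmm <- function(x, ...) x$components

#' One-row fit summary
#'
#' @param x A `freeze_gmm`.
#' @param ... Unused.
#' @export
glance.freeze_gmm <- function(x, ...) {
  tibble(log_likelihood = x$log_likelihood, converged = isTRUE(x$converged),
         n_iter = x$n_iter %||% NA_integer_, n = x$n,
         edge_case = isTRUE(x$edge_case),
         manual_override = isTRUE(x$manual_override), seed = x$seed)
}

#' Serialize / restore a mixture fit
#'
#' Models round-trip through plain JSON so a reviewer's manual overrides are
#' preserved alongside automated fits.
#'
#' @param model A `freeze_gmm`.
#' @param path Output (input) JSON path.
#' @export
write_mixture_json <- function(model, path) {
  payload <- list(
    components = as.list(model$components),
    log_likelihood = model$log_likelihood, converged = model$converged,
    manual_override = model$manual_override, edge_case = model$edge_case,
    edge_case_reasons = model$edge_case_reasons,
    seed = model$seed, n = model$n, trace_sd = model$trace_sd,
    source_id = model$source_id)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_mixture_json
#' @export
read_mixture_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- new_freeze_gmm(weight = p$components$weight, mean = p$components$mean,
                        sd = p$components$sd,
                        log_likelihood = p$log_likelihood %||% NA_real_,
                        converged = p$converged %||% NA,
                        manual_override = isTRUE(p$manual_override),
                        seed = p$seed %||% NA_integer_, n = p$n %||% NA_integer_,
                        trace_sd = p$trace_sd %||% NA_real_,
                        source_id = p$source_id %||% "session")
  out
}
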