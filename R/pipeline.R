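#' Session run configuration
#'
#' Bundles all stage configurations, the input, and reproducibility metadata
#' for one end-to-end session run.
#'
#' @param input A [similarity_trace()], [frame_sequence()], or a path readable
#'   by [read_video()] / [read_trace_csv()].
#' @param denoise A [denoise_config()].
#' @param mixture A [mixture_config()].
#' @param bouts A [bout_config()].
#' @param out_dir Optional output directory; when set, the denoised trace,
#'   bout table, session summary and model JSON are written there, each with
#'   a sidecar carrying the config hash, seed and package version.
#' @param seed Integer seed recorded in every output sidecar and used for the
#'   mixture restarts (overrides `mixture$seed`).
#' @param override_means Optional three component means for the manual path.
#' @param crop Optional crop rectangle passed to [read_video()].
#' @param fps_override Optional fps override for video input.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, denoise = denoise_config(),
                       mixture = mixture_config(), bouts = bout_config(),
                       out_dir = NULL, seed = 1, override_means = NULL,
                       crop = NULL, fps_override = NULL) {
  mixture$seed <- as.integer(seed)
  structure(list(input = input, denoise = denoise, mixture = mixture,
                 bouts = bouts, out_dir = out_dir, seed = as.integer(seed),
                 override_means = override_means, crop = crop,
                 fps_override = fps_override),
            class = "run_config")
}

resolve_trace <- function(cfg) {
  input <- cfg$input
  if (inherits(input, "similarity_trace")) return(input)
  if (inherits(input, "frame_sequence")) return(compute_similarity_trace(input))
  if (is.character(input) && length(input) == 1) {
    if (grepl("\\.csv$", input, ignore.case = TRUE)) {
      return(read_trace_csv(input))
    }
    seq <- read_video(input, fps_override = cfg$fps_override, crop = cfg$crop)
    return(compute_similarity_trace(seq))
  }
  abort("Unrecognized session input.", class = "stillframe_input_error")
}

#' Run the full scoring pipeline on one session
#'
#' Executes, in order: input resolution (video or trace), denoising, mixture
#' fitting, posterior computation, qualifying-frame flagging, bout detection
#' and session summary. If the fitted model is an edge case (the animal
#' nearly always or never moved, so three distinct components cannot be
#' supported) and no `override_means` were supplied, the run stops with
#' status `"review-required"`: no bout table is produced, and frame ranges of
#' diagnostic clips spanning the session are reported for human review. This
#' is deliberate — the method is semi-automated and refuses to auto-score
#' degenerate sessions.
#'
#' @param cfg A [run_config()].
#' @return A list of class `freeze_session`: `status` (`"ok"` or
#'   `"review-required"`), `summary`, `bouts`, `model`, `posterior`, `trace`
#'   (denoised), `flags`, `review_segments` (when review is required), and
#'   `logs` (per-stage timings).
#' @export
run_session <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  logs <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)),
            class = "stillframe_stage_error", parent = e)
    })
    logs[[stage]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  raw <- tick("input", resolve_trace(cfg))
  den <- tick("denoise", denoise(raw, cfg$denoise))
  model <- tick("mixture", {
    tryCatch(fit_mixture(den, cfg$mixture),
             stillframe_degeneracy_error = function(e) {
               if (is.null(cfg$override_means)) NULL else
                 override_components(NULL, cfg$override_means, trace = den)
             })
  })
  needs_override <- is.null(model) ||
    (isTRUE(model$edge_case) && !isTRUE(model$manual_override))
  if (needs_override && !is.null(cfg$override_means)) {
    model <- override_components(model, cfg$override_means, trace = den)
    needs_override <- FALSE
  }
  log_tbl <- function() tibble(stage = names(logs),
                               seconds = unlist(logs, use.names = FALSE))
  if (needs_override) {
    n <- nrow(den)
    starts <- unique(pmax(1L, floor(seq(1, n - 90, length.out = 6))))
    session <- structure(
      list(status = "review-required", summary = NULL, bouts = NULL,
           model = model, posterior = NULL, trace = den, flags = NULL,
           review_segments = tibble(start_index = starts,
                                    end_index = pmin(n, starts + 89L)),
           logs = log_tbl(), config = cfg),
      class = "freeze_session")
    if (!is.null(cfg$out_dir)) write_session_outputs(session, cfg)
    return(session)
  }
  post <- tick("posterior", posterior_trace(model, den))
  flags <- tick("classify", qualifying_frames(post, model, den, cfg$bouts))
  bouts <- detect_bouts(flags, fps = trace_fps(den), cfg = cfg$bouts,
                        source_id = trace_source_id(den))
  summary <- summarize_session(bouts, post)
  session <- structure(
    list(status = "ok", summary = summary, bouts = bouts, model = model,
         posterior = post, trace = den, flags = flags,
         review_segments = NULL, logs = log_tbl(), config = cfg),
    class = "freeze_session")
  if (!is.null(cfg$out_dir)) write_session_outputs(session, cfg)
  session
}

write_session_outputs <- function(session, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  id <- trace_source_id(session$trace)
  meta <- sidecar_meta(cfg[c("denoise", "mixture", "bouts", "override_means")],
                       seed = cfg$seed)
  write_trace_csv(session$trace,
                  file.path(cfg$out_dir, paste0(id, "_trace.csv")), extra = meta)
  if (!is.null(session$model)) {
    write_mixture_json(session$model,
                       file.path(cfg$out_dir, paste0(id, "_model.json")))
  }
  if (identical(session$status, "ok")) {
    write_bouts_csv(session$bouts,
                    file.path(cfg$out_dir, paste0(id, "_bouts.csv")),
                    extra = meta)
    readr::write_csv(session$summary,
                     file.path(cfg$out_dir, paste0(id, "_summary.csv")))
  } else {
    jsonlite::write_json(
      c(list(status = session$status,
             review_segments = session$review_segments), meta),
      file.path(cfg$out_dir, paste0(id, "_REVIEW_REQUIRED.json")),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(session)
}

#' @export
print.freeze_session <- function(x, ...) {
  cat(sprintf("<freeze_session> %s: status %s\n",
              trace_source_id(x$trace), x$status))
  if (identical(x$status, "ok")) print(x$summary)
  else cat("Model needs manual review; see $review_segments.\n")
  invisible(x)
}

#' Run a cohort of sessions and the session-level statistics
#'
#' Scores every session, joins optional per-subject covariates, and runs the
#' cohort analyses: the split-half habituation test, per-minute freezing
#' probabilities with their grand-mean linear trend, and log-transformed
#' Pearson correlations of every covariate against total freezing duration.
#'
#' @param configs List of [run_config()]s (or already-run `freeze_session`s).
#' @param covariates Optional data frame (or CSV path) with a `source_id`
#'   column and numeric covariate columns.
#' @param bin_length_s Bin length for the per-minute analysis (default 60).
#' @return A list of class `freeze_cohort`: `subjects` (tibble), `sessions`,
#'   `split_half`, `trend`, `bin_matrix`, `correlations`, `join_failures`.
#' @export
run_cohort <- function(configs, covariates = NULL, bin_length_s = 60) {
  sessions <- purrr::map(configs, function(cfg) {
    if (inherits(cfg, "freeze_session")) cfg else run_session(cfg)
  })
  ok <- purrr::keep(sessions, ~ identical(.x$status, "ok"))
  if (length(ok) == 0) {
    abort("No session completed automatic scoring.", class = "stillframe_input_error")
  }
  subjects <- purrr::map_dfr(ok, "summary")
  join_failures <- character(0)
  if (!is.null(covariates)) {
    if (is.character(covariates)) {
      covariates <- readr::read_csv(covariates, show_col_types = FALSE)
    }
    join_failures <- setdiff(subjects$source_id, covariates$source_id)
    subjects <- dplyr::left_join(subjects, covariates, by = "source_id")
  }
  bouts_by_subject <- purrr::map(ok, "bouts")
  names(bouts_by_subject) <- subjects$source_id
  n_scores <- purrr::map_int(ok, ~ nrow(.x$trace))
  fps <- purrr::map_dbl(ok, ~ trace_fps(.x$trace))
  session_s <- min(n_scores / fps)
  split_half <- if (length(ok) >= 2) {
    split_half_test(bouts_by_subject, session_s)
  } else NULL
  bins <- purrr::map(ok, ~ minute_bins(.x$bouts, bin_length_s = bin_length_s))
  k <- min(purrr::map_int(bins, nrow))
  bin_matrix <- do.call(rbind, purrr::map(bins, ~ .x$prob[seq_len(k)]))
  rownames(bin_matrix) <- subjects$source_id
  trend <- grand_mean_trend(bin_matrix)
  cov_cols <- if (!is.null(covariates)) {
    setdiff(names(covariates)[vapply(covariates, is.numeric, logical(1))],
            "source_id")
  } else character(0)
  correlations <- purrr::map_dfr(cov_cols, function(col) {
    tryCatch(correlate(subjects, col, "total_freezing_s",
                       log_transform_y = TRUE),
             error = function(e) tibble(estimate = NA_real_, p.value = NA_real_,
                                        conf.low = NA_real_, conf.high = NA_real_,
                                        n = NA_integer_, x = col,
                                        y = "total_freezing_s",
                                        log_transform_y = TRUE))
  })
  structure(list(subjects = subjects, sessions = sessions,
                 split_half = split_half, trend = trend,
                 bin_matrix = bin_matrix, correlations = correlations,
                 join_failures = join_failures),
            class = "freeze_cohort")
}

#' @export
print.freeze_cohort <- function(x, ...) {
  cat(sprintf("<freeze_cohort> %d subjects\n", nrow(x$subjects)))
  print(x$subjects)
  if (!is.null(x$split_half)) {
    cat(sprintf("split-half t(%d) = %.3f, p = %.3f\n", x$split_half$df,
                x$split_half$statistic, x$split_half$p.value))
  }
  if (!isTRUE(x$trend$constant_series)) {
    cat(sprintf("per-bin trend r = %.3f, p = %.3f\n",
                x$trend$estimate, x$trend$p.value))
  }
  invisible(x)
}
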