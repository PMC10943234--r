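#' Write / read a similarity trace as CSV with a JSON sidecar
#'
#' The on-disk dialect is a two-column CSV (`frame_index`, `score`) plus a
#' `<path>.json` sidecar recording `fps`, `source_id`, `n_frames`
#' (`n_scores + 1`) and whether the trace was denoised.
#'
#' @param trace A [similarity_trace()].
#' @param path CSV output path.
#' @param extra Optional named list merged into the sidecar (e.g. seed,
#'   config hash).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, extra = NULL) {
  readr::write_csv(tibble(frame_index = trace$index, score = trace$score), path)
  sidecar <- c(list(fps = trace_fps(trace), source_id = trace_source_id(trace),
                    n_frames = nrow(trace) + 1L,
                    denoised = isTRUE(attr(trace, "denoised"))), extra)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) {
    jsonlite::read_json(side_path, simplifyVector = TRUE)
  } else {
    list()
  }
  similarity_trace(d$score, fps = side$fps %||% 30,
                   source_id = side$source_id %||%
                     sub("\\.[A-Za-z0-9]+$", "", basename(path)),
                   denoised = isTRUE(side$denoised))
}

#' Write a bout table as CSV
#'
#' Columns: `source_id`, `bout`, `start_index`, `end_index`, `start_s`,
#' `duration_s`.
#'
#' @param bouts A `bout_table`.
#' @param path CSV output path.
#' @param extra Optional named list merged into the JSON sidecar.
#' @export
write_bouts_csv <- function(bouts, path, extra = NULL) {
  readr::write_csv(
    dplyr::mutate(as_tibble(bouts),
                  source_id = attr(bouts, "source_id") %||% "session",
                  .before = 1),
    path)
  sidecar <- c(list(fps = attr(bouts, "fps"), n_scores = attr(bouts, "n_scores"),
                    source_id = attr(bouts, "source_id")), extra)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_meta <- function(cfg, seed = NULL) {
  list(config_hash = rlang::hash(cfg),
       seed = seed,
       package_version = as.character(utils::packageVersion("stillframe")))
}
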