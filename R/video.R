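#' Read a video into grayscale frames
#'
#' Reads a single-subject fixed-camera recording into a [frame_sequence()].
#' Three sources are supported:
#'
#' * a directory of per-frame image files (`.png`, `.tif`/`.tiff`), ordered by
#'   file name — the common export format of frame-grabber pipelines;
#' * a multi-frame TIFF stack;
#' * an MP4/AVI container, decoded by piping through an `ffmpeg` binary when
#'   one is on the `PATH`.
#'
#' Color input is converted to grayscale with ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114), so achromatic pixels keep their value. Intensities
#' are kept on the scale the decoder produces (`[0, 1]` for png/tiff);
#' similarity scoring is scale-invariant.
#'
#' @param path File or directory path.
#' @param fps_override Optional fps to use instead of container metadata
#'   (image sequences have no metadata and default to 30).
#' @param max_dim Optional maximum of width/height in pixels; larger frames
#'   are downsampled preserving aspect ratio (nearest-neighbor). Default off:
#'   raw frames are scored.
#' @param crop Optional integer vector `c(row_min, row_max, col_min, col_max)`
#'   restricting scoring to a rectangular region (e.g. the cage interior).
#' @param source_id Identifier recorded on the sequence; defaults to the file
#'   base name.
#' @return A [frame_sequence()].
#' @export
read_video <- function(path, fps_override = NULL, max_dim = NULL, crop = NULL,
                       source_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Input not found: %s", path), class = "stillframe_decode_error")
  }
  source_id <- source_id %||% sub("\\.[A-Za-z0-9]+$", "", basename(path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    files <- sort(files)
    if (length(files) < 2) {
      abort("Fewer than 2 frame images found.", class = "stillframe_input_error")
    }
    frames <- lapply(files, read_image_gray)
    fps <- fps_override %||% 30
  } else if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    frames <- read_tiff_stack(path)
    fps <- fps_override %||% 30
  } else {
    frames <- read_container_ffmpeg(path)
    fps <- fps_override %||% attr(frames, "fps") %||% 30
  }
  if (length(frames) < 2) {
    abort("Video has fewer than 2 frames.", class = "stillframe_input_error")
  }
  if (!is.null(crop)) {
    frames <- lapply(frames, function(f)
      f[crop[1]:crop[2], crop[3]:crop[4], drop = FALSE])
  }
  if (!is.null(max_dim)) {
    frames <- lapply(frames, downsample_frame, max_dim = max_dim)
  }
  frame_sequence(frames, fps = fps, source_id = source_id)
}

# BT.601 luma; accepts HxW, HxWx3 or HxWx4 arrays on any intensity scale
luma_gray <- function(img) {
  if (length(dim(img)) == 2) return(img)
  if (length(dim(img)) == 3) {
    w <- c(0.299, 0.587, 0.114)
    return(img[, , 1] * w[1] + img[, , 2] * w[2] + img[, , 3] * w[3])
  }
  abort("Unsupported image array shape.", class = "stillframe_decode_error")
}

read_image_gray <- function(file) {
  img <- if (grepl("\\.png$", file, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("Package 'png' is required to read PNG frames.",
            class = "stillframe_decode_error")
    }
    png::readPNG(file)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("Package 'tiff' is required to read TIFF frames.",
            class = "stillframe_decode_error")
    }
    tiff::readTIFF(file)
  }
  luma_gray(img)
}

read_tiff_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("Package 'tiff' is required to read TIFF stacks.",
          class = "stillframe_decode_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, luma_gray)
}

read_container_ffmpeg <- function(path) {
  ffmpeg <- Sys.which("ffmpeg")
  if (!nzchar(ffmpeg)) {
    abort(paste0("Cannot decode '", path, "': no ffmpeg binary on PATH and ",
                 "the file is not an image sequence or TIFF stack."),
          class = "stillframe_decode_error")
  }
  probe <- Sys.which("ffprobe")
  meta_fps <- NULL
  dims <- NULL
  if (nzchar(probe)) {
    out <- suppressWarnings(system2(
      probe, c("-v", "error", "-select_streams", "v:0", "-show_entries",
               "stream=width,height,r_frame_rate", "-of", "csv=p=0",
               shQuote(path)), stdout = TRUE))
    parts <- strsplit(out[1], ",")[[1]]
    if (length(parts) >= 3) {
      dims <- as.integer(parts[1:2])
      rate <- strsplit(parts[3], "/")[[1]]
      meta_fps <- as.numeric(rate[1]) / as.numeric(rate[2])
    }
  }
  if (is.null(dims)) {
    abort("Could not probe video dimensions.", class = "stillframe_decode_error")
  }
  raw_file <- tempfile(fileext = ".gray")
  status <- suppressWarnings(system2(
    ffmpeg, c("-v", "error", "-i", shQuote(path), "-f", "rawvideo",
              "-pix_fmt", "gray", shQuote(raw_file))))
  if (status != 0 || !file.exists(raw_file)) {
    abort("ffmpeg failed to decode the video.", class = "stillframe_decode_error")
  }
  on.exit(unlink(raw_file))
  bytes <- readBin(raw_file, "raw", n = file.size(raw_file))
  px <- as.integer(bytes)
  nper <- dims[1] * dims[2]
  nframes <- length(px) %/% nper
  frames <- lapply(seq_len(nframes), function(i) {
    matrix(px[((i - 1) * nper + 1):(i * nper)], nrow = dims[2], ncol = dims[1],
           byrow = TRUE)
  })
  attr(frames, "fps") <- meta_fps
  frames
}

downsample_frame <- function(f, max_dim) {
  d <- dim(f)
  if (max(d) <= max_dim) return(f)
  scale <- max_dim / max(d)
  nr <- max(1L, floor(d[1] * scale))
  nc <- max(1L, floor(d[2] * scale))
  ri <- pmin(d[1], floor(seq(0.5, d[1] - 0.5, length.out = nr)) + 1L)
  ci <- pmin(d[2], floor(seq(0.5, d[2] - 0.5, length.out = nc)) + 1L)
  f[ri, ci, drop = FALSE]
}
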