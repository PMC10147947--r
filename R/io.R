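# Reading and writing the standard interchange formats: multipage TIFF / PNG
# sequences for frame stacks, CSV + JSON sidecar for traces, JSON for ground
# truth, beat tables and reports.

#' Write a frame stack
#'
#' `write_frames()` writes either a multipage grayscale TIFF (when `path`
#' ends in `.tif`/`.tiff`) or a numbered PNG sequence (when `path` is a
#' directory or a `printf`-style pattern such as `frames/%04d.png`).
#'
#' @param stack A [frame_stack()].
#' @param path Output path (see above).
#' @param bits Bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_frames <- function(stack, path, bits = 8) {
  stopifnot(inherits(stack, "frame_stack"), bits %in% c(8, 16))
  f <- stack$frames / 255                     # grey levels -> [0, 1]
  nt <- dim(f)[3]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- lapply(seq_len(nt), function(i) f[, , i])
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else {
    pattern <- if (grepl("%", path, fixed = TRUE)) path
               else file.path(path, "frame%05d.png")
    dir.create(dirname(pattern), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nt))
      png::writePNG(f[, , i], sprintf(pattern, i - 1L))
  }
  invisible(path)
}

#' Read a frame stack
#'
#' Reads a multipage TIFF or a numbered PNG sequence back into a
#' [frame_stack()]. Grey values are rescaled to 0--255. Frame rate and pixel
#' size are not stored in the image files and must be supplied.
#'
#' @param path A `.tif`/`.tiff` file, a directory of `.png` frames (sorted
#'   lexicographically), or a character vector of frame files.
#' @param fps Frame rate, frames/s.
#' @param pixel_size Pixel pitch, um/px.
#' @param origin_mm Tube coordinate of the left image edge, mm.
#' @return A [frame_stack()].
#' @export
read_frames <- function(path, fps, pixel_size = NA_real_, origin_mm = 0) {
  if (length(path) == 1L && dir.exists(path))
    path <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(path) == 1L &&
      tolower(tools::file_ext(path)) %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  } else {
    pages <- lapply(path, png::readPNG)
  }
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  frame_stack(frames * 255, fps = fps, pixel_size = pixel_size,
              origin_mm = origin_mm)
}

# strip S3 classes recursively so jsonlite serializes plain lists
unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}

#' Write / read ground truth as JSON
#'
#' @param truth A `heart_truth` from [simulate_heart()].
#' @param path JSON file path.
#' @return `write_truth()`: `path`, invisibly. `read_truth()`: the truth
#'   record as a list.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "heart_truth"))
  jsonlite::write_json(unclass_deep(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read a contraction trace
#'
#' The trace goes to CSV with header
#' `frame,time_s,raw_count,normalized,smoothed`; the extraction metadata
#' (threshold, window, ROI, fps, pixel size) goes to a JSON sidecar at
#' `<path>.json` so every result is auditable.
#'
#' @param trace A `contraction_trace`.
#' @param path CSV file path.
#' @return `write_trace()`: `path`, invisibly. `read_trace()`: the
#'   `contraction_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "contraction_trace"))
  df <- data.frame(frame = trace$frame, time_s = trace$time,
                   raw_count = trace$raw, normalized = trace$normalized,
                   smoothed = trace$smoothed)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fps = attr(trace, "fps"), window = attr(trace, "window"),
               roi = unclass(attr(trace, "roi")),
               threshold_used = attr(trace, "threshold_used"),
               pixel_size = attr(trace, "pixel_size"),
               roi_convention = "0-based, half-open [col0, col0+width)")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- data.frame(frame = df$frame, time = df$time_s, raw = df$raw_count,
                    normalized = df$normalized, smoothed = df$smoothed)
  attr(out, "fps") <- meta$fps
  attr(out, "window") <- meta$window
  attr(out, "roi") <- do.call(roi_rect, as.list(meta$roi))
  attr(out, "threshold_used") <- meta$threshold_used
  attr(out, "pixel_size") <- meta$pixel_size
  class(out) <- c("contraction_trace", "data.frame")
  out
}
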