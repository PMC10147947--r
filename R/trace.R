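# Contraction-trace extraction: threshold the stack, count foreground pixels
# per frame in a region of interest, normalize to [0, 1] and smooth with a
# centred moving average. Re-implements the pixel-count-plus-spreadsheet
# post-processing workflow common in semi-automated heart-rate video analysis.

#' Construct a frame stack
#'
#' @param frames Numeric 3D array `[row, col, time]` of grey levels.
#' @param fps Frame rate, frames per second.
#' @param pixel_size Pixel pitch, micrometres per pixel.
#' @param origin_mm Tube coordinate of the left image edge, mm (0 when the
#'   image covers the full object).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps, pixel_size = NA_real_, origin_mm = 0) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a 3D array [row, col, time]", call. = FALSE)
  if (dim(frames)[3] < 2L) stop("need at least 2 frames", call. = FALSE)
  stopifnot(is.numeric(fps), fps > 0)
  structure(list(frames = frames, fps = fps, pixel_size = pixel_size,
                 origin_mm = origin_mm),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %d x %d px, %g fps (%.1f s)\n",
              d[3], d[1], d[2], x$fps, d[3] / x$fps))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

# Otsu threshold on a pooled grey-level histogram (0-255, 256 bins):
# maximizes the between-class variance of background vs foreground.
otsu_level <- function(values) {
  v <- as.integer(pmin(pmax(values, 0), 255))
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  valid <- omega > 0 & omega < 1
  if (!any(valid))
    stop("degenerate image: zero-variance histogram", call. = FALSE)
  sigma_b <- rep(-Inf, 256)
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  levels[which.max(sigma_b)]
}

#' Threshold a frame stack
#'
#' Binarizes every frame with a single global threshold: a pixel is
#' foreground iff its grey value is strictly greater than the threshold.
#' With `method = "otsu"` the threshold is computed once from the pooled
#' histogram of the whole stack, so frame-to-frame count changes reflect
#' geometry only, never a drifting per-frame threshold.
#'
#' @param stack A [frame_stack()].
#' @param method `"otsu"` or a fixed numeric grey level.
#' @return List with `binary` (logical array of the stack's dimensions) and
#'   `threshold` (the grey level used).
#' @export
threshold_frames <- function(stack, method = "otsu") {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.numeric(method)) {
    thr <- method
  } else if (identical(method, "otsu")) {
    rng <- range(stack$frames)
    if (diff(rng) == 0)
      stop("degenerate image: zero-variance histogram", call. = FALSE)
    thr <- otsu_level(stack$frames)
  } else stop("method must be 'otsu' or a numeric level", call. = FALSE)
  list(binary = stack$frames > thr, threshold = thr)
}

#' Count foreground pixels per frame in a region of interest
#'
#' @param binary Logical array `[row, col, time]` (from [threshold_frames()]).
#' @param roi A [roi_rect()] lying fully inside the frames.
#' @return Integer vector of per-frame counts (length = number of frames).
#' @export
count_foreground <- function(binary, roi) {
  stopifnot(is.logical(binary), length(dim(binary)) == 3L,
            inherits(roi, "roi_rect"))
  d <- dim(binary)
  if (roi$row0 + roi$height > d[1] || roi$col0 + roi$width > d[2])
    stop("ROI extends outside the frames", call. = FALSE)
  rows <- roi$row0 + seq_len(roi$height)   # 0-based roi -> 1-based index
  cols <- roi$col0 + seq_len(roi$width)
  as.integer(colSums(binary[rows, cols, , drop = FALSE], dims = 2L))
}

#' Min-max normalization to [0, 1]
#'
#' `(x - min) / (max - min)`; invariant under positive affine transforms of
#' the input.
#'
#' @param x Numeric vector with `max(x) > min(x)`.
#' @return Vector in `[0, 1]` with minimum 0 and maximum 1.
#' @export
normalize01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) stop("degenerate trace: constant signal", call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

#' Centred moving average
#'
#' Symmetric moving average of width `window` samples. Odd windows are plain
#' centred means over `[i - k, i + k]`. Even windows use the standard
#' half-weight centred form (weights `1/2, 1, ..., 1, 1/2` over
#' `[i - w/2, i + w/2]`, divided by `w`), which keeps the filter symmetric —
#' linear ramps pass through unchanged. Near the edges the window shrinks to
#' the largest symmetric plain mean available, so no values are fabricated
#' beyond the trace; output length equals input length.
#'
#' @param x Numeric vector.
#' @param window Width in samples, `1 <= window <= length(x)`.
#' @return Smoothed vector, same length as `x`.
#' @export
moving_average <- function(x, window = 20) {
  n <- length(x)
  if (window < 1 || window %% 1 != 0)
    stop("window must be a positive integer", call. = FALSE)
  if (window > n) stop("window exceeds trace length", call. = FALSE)
  if (window == 1) return(x)
  if (window %% 2 == 0) {
    k <- window / 2
    wts <- c(0.5, rep(1, window - 1), 0.5) / window
  } else {
    k <- (window - 1) / 2
    wts <- rep(1, window) / window
  }
  out <- as.numeric(stats::filter(x, wts, sides = 2))
  # shrink to the largest symmetric plain mean near the edges
  for (i in which(is.na(out))) {
    h <- min(i - 1, n - i)
    out[i] <- mean(x[(i - h):(i + h)])
  }
  # a convex average lies within the input range; guard the invariant
  # against floating-point accumulation in the filter
  pmin(pmax(out, min(x)), max(x))
}

#' Extract a contraction trace from a frame stack
#'
#' Full measurement chain for one region of interest: global thresholding,
#' per-frame foreground pixel counting, min-max normalization of the whole
#' series to [0, 1], and centred moving-average smoothing. On an area trace
#' the systole (narrowest tube) is the trace minimum.
#'
#' @param stack A [frame_stack()].
#' @param roi A [roi_rect()].
#' @param threshold `"otsu"` (pooled-histogram threshold, the default) or a
#'   fixed numeric grey level.
#' @param window Moving-average width in samples (default 20).
#' @return A `contraction_trace`: data frame with columns `frame` (0-based),
#'   `time` (s), `raw` (pixel count), `normalized` and `smoothed`, plus
#'   attributes `fps`, `window`, `roi`, `threshold_used` and `pixel_size`.
#' @export
extract_trace <- function(stack, roi, threshold = "otsu", window = 20) {
  stopifnot(inherits(stack, "frame_stack"), inherits(roi, "roi_rect"))
  th <- threshold_frames(stack, threshold)
  raw <- count_foreground(th$binary, roi)
  norm <- normalize01(raw)
  sm <- moving_average(norm, window)
  n <- length(raw)
  out <- data.frame(frame = seq_len(n) - 1L,
                    time = (seq_len(n) - 1L) / stack$fps,
                    raw = raw, normalized = norm, smoothed = sm)
  attr(out, "fps") <- stack$fps
  attr(out, "window") <- window
  attr(out, "roi") <- roi
  attr(out, "threshold_used") <- th$threshold
  attr(out, "pixel_size") <- stack$pixel_size
  class(out) <- c("contraction_trace", "data.frame")
  out
}

#' @export
print.contraction_trace <- function(x, ...) {
  cat(sprintf(
    "contraction_trace: %d samples at %g fps (%.1f s), threshold %s, window %d\n",
    nrow(x), attr(x, "fps"), nrow(x) / attr(x, "fps"),
    format(attr(x, "threshold_used")), attr(x, "window")))
  invisible(x)
}

#' @export
plot.contraction_trace <- function(x, ...) {
  graphics::plot(x$time, x$normalized, type = "l", col = "grey70",
                 xlab = "time (s)", ylab = "normalized foreground area", ...)
  graphics::lines(x$time, x$smoothed, col = "firebrick", lwd = 1.5)
  invisible(x)
}

#' Place an ROI over a tube segment
#'
#' Builds a full-height [roi_rect()] covering `width_mm` of tube centred at
#' axial position `center_mm` (tube coordinates), given the stack's pixel
#' size and image origin.
#'
#' @param stack A [frame_stack()] with known `pixel_size`.
#' @param center_mm ROI centre along the tube, mm.
#' @param width_mm ROI width, mm.
#' @return A [roi_rect()].
#' @export
roi_for_segment <- function(stack, center_mm, width_mm) {
  stopifnot(inherits(stack, "frame_stack"), is.finite(stack$pixel_size))
  px_mm <- stack$pixel_size / 1000
  d <- dim(stack$frames)
  w <- max(1L, as.integer(round(width_mm / px_mm)))
  c0 <- as.integer(round((center_mm - stack$origin_mm) / px_mm - w / 2))
  if (c0 < 0 || c0 + w > d[2])
    stop("requested segment lies outside the imaged field of view",
         call. = FALSE)
  roi_rect(col0 = c0, row0 = 0L, width = w, height = d[1])
}
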