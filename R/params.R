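#' Per-beat contraction waveform parameters
#'
#' The radius of the tube during one contraction follows a piecewise-linear
#' (trapezoidal) waveform with four phases: contraction (phase I, duration
#' `d1`), contraction-peak plateau (phase II, `d2`), expansion (phase III,
#' `d3`) and the maximum-expansion plateau (phase IV, the remainder of the
#' inter-beat interval). The trapezoid is chosen over smoother shapes because
#' it admits exact analytic oracles for phase durations and slopes.
#'
#' @param d1 Duration of phase I (contraction), seconds.
#' @param d2 Duration of phase II (contraction-peak plateau), seconds.
#' @param d3 Duration of phase III (expansion), seconds. Must exceed `d1`:
#'   in the species this emulates, contraction is faster (steeper) than
#'   re-expansion.
#' @param amplitude_ratio End-systolic over end-diastolic radius,
#'   dimensionless in (0, 1). Default 0.5: at full systole the tube diameter
#'   is about half the diastolic diameter.
#' @return An object of class `waveform_params`.
#' @export
waveform_params <- function(d1 = 0.35, d2 = 0.15, d3 = 0.70,
                            amplitude_ratio = 0.5) {
  stopifnot(is.numeric(d1), is.numeric(d2), is.numeric(d3),
            length(d1) == 1L, length(d2) == 1L, length(d3) == 1L)
  if (d1 <= 0 || d2 <= 0 || d3 <= 0)
    stop("phase durations d1, d2, d3 must all be positive", call. = FALSE)
  if (d1 >= d3)
    stop("d1 must be smaller than d3 (contraction steeper than expansion)",
         call. = FALSE)
  if (amplitude_ratio <= 0 || amplitude_ratio >= 1)
    stop("amplitude_ratio must lie strictly between 0 and 1", call. = FALSE)
  structure(list(d1 = d1, d2 = d2, d3 = d3,
                 amplitude_ratio = amplitude_ratio),
            class = "waveform_params")
}

#' Beat schedule parameters
#'
#' Describes the intermittent rhythm: runs ("bursts") of beats at a fixed
#' within-burst inter-beat interval, separated by prolonged pauses. A pause
#' is a full inter-onset gap (trough-to-trough), not an increment over the
#' normal interval, so the logged gap is directly comparable to a measured
#' trough-to-trough pause duration.
#'
#' @param ibi Within-burst inter-beat interval, seconds.
#' @param beats_per_burst Number of beats per burst: a positive integer, an
#'   integer vector cycled over successive bursts (e.g. `c(8, 9)` alternates
#'   8- and 9-beat bursts), or `Inf` for an uninterrupted periodic rhythm.
#' @param pause_model Either `pause_fixed(gap)` for a constant inter-burst
#'   gap or `pause_lognormal(mean, sd, floor)` for lognormally distributed
#'   gaps truncated below at `floor`.
#' @param duration Total schedule duration, seconds. Must exceed `3 * ibi`.
#' @param seed Integer seed for the (schedule) random substream.
#' @return An object of class `schedule_params`.
#' @export
schedule_params <- function(ibi = 1.519,
                            beats_per_burst = c(8, 9),
                            pause_model = pause_lognormal(3.4, 2.1, floor = 2),
                            duration = 60,
                            seed = 1L) {
  stopifnot(is.numeric(ibi), length(ibi) == 1L, ibi > 0)
  stopifnot(is.numeric(duration), length(duration) == 1L)
  if (duration <= 3 * ibi)
    stop("duration must exceed 3 * ibi", call. = FALSE)
  if (!is.numeric(beats_per_burst) || length(beats_per_burst) < 1L ||
      any(beats_per_burst < 1))
    stop("beats_per_burst must be positive", call. = FALSE)
  finite_bpb <- is.finite(beats_per_burst)
  if (any(finite_bpb) && any(beats_per_burst[finite_bpb] %% 1 != 0))
    stop("beats_per_burst must be whole numbers (or Inf)", call. = FALSE)
  if (!inherits(pause_model, "pause_model"))
    stop("pause_model must be pause_fixed() or pause_lognormal()",
         call. = FALSE)
  if (pause_model$floor <= ibi)
    stop("pause floor/gap must exceed the inter-beat interval", call. = FALSE)
  structure(list(ibi = ibi, beats_per_burst = beats_per_burst,
                 pause_model = pause_model, duration = duration,
                 seed = as.integer(seed)),
            class = "schedule_params")
}

#' @rdname schedule_params
#' @param gap Fixed inter-burst gap (trough-to-trough), seconds.
#' @export
pause_fixed <- function(gap) {
  stopifnot(is.numeric(gap), length(gap) == 1L, gap > 0)
  structure(list(kind = "fixed", gap = gap, floor = gap),
            class = "pause_model")
}

#' @rdname schedule_params
#' @param mean,sd Natural-scale mean and standard deviation of the lognormal
#'   gap distribution, seconds.
#' @param floor Lower truncation of drawn gaps, seconds; must exceed the
#'   inter-beat interval so a pause is always distinguishable from a beat.
#' @export
pause_lognormal <- function(mean, sd, floor) {
  stopifnot(mean > 0, sd >= 0, floor > 0)
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  structure(list(kind = "lognormal", mean = mean, sd = sd, floor = floor,
                 meanlog = meanlog, sdlog = sdlog),
            class = "pause_model")
}

#' Tube geometry, imaging and rendering parameters
#'
#' Geometry of the contracting tube and of the virtual camera. The contraction
#' wave travels anterograde (posterior to anterior, i.e. from `x = 0` toward
#' `x = length`) at constant speed with no dispersion or amplitude decay.
#' The camera images a field of view `[fov_offset, fov_offset + fov_length]`
#' along the tube (the whole tube by default); real recordings typically
#' capture only a few millimetres of the heart.
#'
#' @param length Tube length, mm.
#' @param r_max End-diastolic (fully dilated) radius, micrometres.
#' @param r_min End-systolic (fully contracted) radius, micrometres.
#' @param wave_speed Peristaltic wave speed, mm/s, anterograde.
#' @param pixel_size Pixel pitch, micrometres per pixel.
#' @param fps Frame rate, frames per second.
#' @param noise_sd Gaussian pixel-noise standard deviation, grey levels
#'   (0 disables noise).
#' @param foreground_level,background_level Grey levels of tube and
#'   background on the 0--255 scale.
#' @param fov_offset,fov_length Imaged window along the tube, mm.
#' @param height_px Frame height in pixels; must fit the dilated tube.
#' @return An object of class `tube_geometry`.
#' @export
tube_geometry <- function(length = 18, r_max = 80, r_min = 40,
                          wave_speed = 8.9286, pixel_size = 20, fps = 24,
                          noise_sd = 0, foreground_level = 255,
                          background_level = 0,
                          fov_offset = 0, fov_length = length,
                          height_px = NULL) {
  stopifnot(length > 0, r_max > 0, wave_speed > 0, fps > 0, pixel_size > 0)
  if (r_min <= 0 || r_min >= r_max)
    stop("need r_max > r_min > 0", call. = FALSE)
  if (foreground_level <= background_level)
    stop("foreground_level must exceed background_level", call. = FALSE)
  if (fov_offset < 0 || fov_offset + fov_length > length + 1e-9)
    stop("field of view must lie within the tube", call. = FALSE)
  if (is.null(height_px))
    height_px <- 2L * as.integer(ceiling(2 * r_max / pixel_size))
  height_px <- as.integer(height_px)
  if (height_px * pixel_size < 2 * r_max)
    stop("image too small to contain the dilated tube (2 * r_max)",
         call. = FALSE)
  structure(list(length = length, r_max = r_max, r_min = r_min,
                 wave_speed = wave_speed, pixel_size = pixel_size, fps = fps,
                 noise_sd = noise_sd, foreground_level = foreground_level,
                 background_level = background_level,
                 fov_offset = fov_offset, fov_length = fov_length,
                 height_px = height_px),
            class = "tube_geometry")
}

#' Rectangular region of interest
#'
#' 0-based, half-open pixel rectangle: columns `[col0, col0 + width)`, rows
#' `[row0, row0 + height)`.
#'
#' @param col0,row0 Top-left corner, 0-based pixels.
#' @param width,height Extent in pixels, at least 1.
#' @return An object of class `roi_rect`.
#' @export
roi_rect <- function(col0, row0, width, height) {
  stopifnot(col0 >= 0, row0 >= 0, width >= 1, height >= 1,
            col0 %% 1 == 0, row0 %% 1 == 0, width %% 1 == 0, height %% 1 == 0)
  structure(list(col0 = as.integer(col0), row0 = as.integer(row0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi_rect")
}

#' Cylindrical cardiac geometry
#'
#' The heart lumen is modelled as a cylinder whose radius oscillates between
#' an end-diastolic maximum and an end-systolic minimum.
#'
#' @param r_max End-diastolic radius, mm.
#' @param r_min End-systolic radius, mm.
#' @param length Heart length, mm.
#' @return An object of class `cardiac_geometry`.
#' @export
cardiac_geometry <- function(r_max = 0.08, r_min = 0.04, length = 18) {
  if (!(r_max >= r_min && r_min > 0))
    stop("need r_max >= r_min > 0", call. = FALSE)
  if (length <= 0) stop("length must be positive", call. = FALSE)
  structure(list(r_max = r_max, r_min = r_min, length = length),
            class = "cardiac_geometry")
}
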