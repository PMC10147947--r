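# Synthetic peristaltic-heart video generator.
#
# A bright contracting tube on a dark background: beats arrive in bursts
# separated by prolonged pauses, each beat follows a trapezoidal radius
# waveform, and the contraction travels anterograde (x = 0 posterior) at a
# constant speed, so regions further anterior contract later.

# Evaluate the unimodal piecewise-linear contraction waveform w(s) in [0, 1]:
# 0 -> 1 over d1, hold over d2, 1 -> 0 over d3, 0 outside the support.
waveform_value <- function(s, wf) {
  w <- numeric(length(s))
  up <- s >= 0 & s < wf$d1
  hold <- s >= wf$d1 & s < wf$d1 + wf$d2
  down <- s >= wf$d1 + wf$d2 & s < wf$d1 + wf$d2 + wf$d3
  w[up] <- s[up] / wf$d1
  w[hold] <- 1
  w[down] <- (wf$d1 + wf$d2 + wf$d3 - s[down]) / wf$d3
  w
}

# Run code with a private RNG state so generator seeding never disturbs the
# caller's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a beat schedule with bursts and pauses
#'
#' Lays out contraction onset times at the posterior reference end (`x = 0`)
#' of the tube: bursts of beats at the within-burst inter-beat interval,
#' separated by pause gaps drawn from the schedule's pause model. A pause gap
#' is a full inter-onset interval (it replaces, not extends, a beat interval).
#' The realized gaps are logged exactly, so downstream pause statistics can be
#' checked against ground truth.
#'
#' @param params A [schedule_params()] object.
#' @return An object of class `heart_schedule` with elements `onsets`
#'   (strictly increasing onset times in seconds, covering `[0, duration)`),
#'   `pause_gaps` (realized gap durations), `pause_after` (index of the onset
#'   preceding each gap) and `params`.
#' @examples
#' sch <- build_schedule(schedule_params(ibi = 1.6, beats_per_burst = Inf,
#'                                       duration = 8))
#' sch$onsets  # 0.0 1.6 3.2 4.8 6.4
#' @export
build_schedule <- function(params) {
  stopifnot(inherits(params, "schedule_params"))
  ibi <- params$ibi
  dur <- params$duration
  bpb <- params$beats_per_burst

  if (all(is.infinite(bpb))) {
    n_on <- floor(dur / ibi - 1e-9) + 1L   # onsets strictly inside [0, dur)
    onsets <- (seq_len(n_on) - 1L) * ibi
    out <- list(onsets = onsets, pause_gaps = numeric(0),
                pause_after = integer(0), params = params)
    class(out) <- "heart_schedule"
    return(out)
  }
  if (is.finite(bpb[1]) && (bpb[1] - 1) * ibi >= dur)
    stop("degenerate schedule: duration too short for one burst",
         call. = FALSE)

  draw_gap <- function(pm) {
    if (pm$kind == "fixed") return(pm$gap)
    max(pm$floor, stats::rlnorm(1, meanlog = pm$meanlog, sdlog = pm$sdlog))
  }

  with_seed(params$seed, {
    onsets <- numeric(0)
    gaps <- numeric(0)
    gap_after <- integer(0)
    t <- 0
    burst <- 0L
    repeat {
      burst <- burst + 1L
      n_beats <- bpb[(burst - 1L) %% length(bpb) + 1L]
      k <- 0L
      while (k < n_beats && t < dur) {
        onsets <- c(onsets, t)
        k <- k + 1L
        if (k < n_beats) t <- t + ibi
      }
      if (t >= dur || length(onsets) == 0) break
      g <- draw_gap(params$pause_model)
      t <- t + g
      if (t >= dur) break
      gaps <- c(gaps, g)
      gap_after <- c(gap_after, length(onsets))
    }
    out <- list(onsets = onsets, pause_gaps = gaps,
                pause_after = gap_after, params = params)
    class(out) <- "heart_schedule"
    out
  })
}

#' @export
print.heart_schedule <- function(x, ...) {
  cat("Heart beat schedule:", length(x$onsets), "onsets over",
      format(x$params$duration), "s;", length(x$pause_gaps), "pause gaps\n")
  if (length(x$pause_gaps))
    cat("  gap mean", format(mean(x$pause_gaps), digits = 3), "s, sd",
        format(stats::sd(x$pause_gaps), digits = 3), "s\n")
  invisible(x)
}

#' Programmed lag between two axial positions
#'
#' The contraction wave travels anterograde at constant speed, so a point at
#' axial position `x_b` contracts `(x_b - x_a) / wave_speed` seconds after a
#' point at `x_a`.
#'
#' @param geom A [tube_geometry()].
#' @param x_a,x_b Axial positions, mm (`x = 0` is posterior).
#' @return Lag in seconds (positive when `x_b` is anterior to `x_a`).
#' @export
programmed_lag <- function(geom, x_a, x_b) {
  stopifnot(inherits(geom, "tube_geometry"))
  (x_b - x_a) / geom$wave_speed
}

#' Tube radius at position x and time t
#'
#' Evaluates the radius field
#' `r(x, t) = r_max - (r_max - r_min) * w(t - onset_k - x / wave_speed)`
#' where `w` is the trapezoidal contraction waveform and `onset_k` the latest
#' onset whose delayed waveform support contains `t`. Because waveform
#' support never exceeds the inter-beat interval, at most one beat is active
#' at any `(x, t)`.
#'
#' @param schedule A `heart_schedule` from [build_schedule()].
#' @param waveform A [waveform_params()].
#' @param geom A [tube_geometry()].
#' @param x Axial position(s), mm, in `[0, length]`.
#' @param t Time(s), seconds. `x` and `t` are recycled to a common length.
#' @return Radius in micrometres, vectorized.
#' @export
radius_field <- function(schedule, waveform, geom, x, t) {
  stopifnot(inherits(schedule, "heart_schedule"),
            inherits(waveform, "waveform_params"),
            inherits(geom, "tube_geometry"))
  if (any(x < 0 | x > geom$length))
    stop("x out of range [0, length]", call. = FALSE)
  n <- max(length(x), length(t))
  x <- rep_len(x, n)
  t <- rep_len(t, n)
  t_eff <- t - x / geom$wave_speed
  idx <- findInterval(t_eff, schedule$onsets)
  s <- rep(-1, n)                      # outside support => w = 0
  act <- idx >= 1L
  s[act] <- t_eff[act] - schedule$onsets[idx[act]]
  w <- waveform_value(s, waveform)
  geom$r_max - (geom$r_max - geom$r_min) * w
}

#' Render a synthetic frame stack
#'
#' Draws the tube as a horizontal bright band of half-width
#' `r(x, t) / pixel_size` pixels around a fixed midline, sampled per pixel
#' column, over `round(duration * fps)` frames. The midline sits on a row
#' boundary and a pixel is foreground when its row centre lies strictly
#' within the band, so an integer half-width of `h` pixels rasters to exactly
#' `2 h` foreground pixels per column (hard edges, no anti-aliasing:
#' thresholding is exactly invertible). Optional Gaussian pixel noise is
#' seeded from the schedule seed on an independent substream and values are
#' clipped to the 0--255 grey range.
#'
#' @param schedule A `heart_schedule`.
#' @param waveform A [waveform_params()].
#' @param geom A [tube_geometry()]; its `fov_offset`/`fov_length` select the
#'   imaged window along the tube.
#' @return A `frame_stack`: list with `frames` (numeric array
#'   `[row, col, time]`, grey levels 0--255), `fps`, `pixel_size` (um/px) and
#'   `origin_mm` (tube coordinate of the left image edge).
#' @export
render_frames <- function(schedule, waveform, geom) {
  stopifnot(inherits(schedule, "heart_schedule"),
            inherits(geom, "tube_geometry"))
  dur <- schedule$params$duration
  n_frames <- round(dur * geom$fps)
  if (n_frames < 2) stop("frame count must be at least 2", call. = FALSE)
  px_mm <- geom$pixel_size / 1000
  n_col <- as.integer(round(geom$fov_length / px_mm))
  n_row <- geom$height_px
  if (n_row * geom$pixel_size < 2 * geom$r_max)
    stop("image too small to contain 2 * r_max", call. = FALSE)

  x_mm <- geom$fov_offset + (seq_len(n_col) - 0.5) * px_mm  # column centres
  row_centre <- seq_len(n_row) - 0.5
  mid <- n_row / 2                       # midline on a row boundary
  t_frames <- (seq_len(n_frames) - 1) / geom$fps

  frames <- array(geom$background_level, dim = c(n_row, n_col, n_frames))
  for (i in seq_len(n_frames)) {
    r_um <- radius_field(schedule, waveform, geom, x_mm, t_frames[i])
    h_px <- r_um / geom$pixel_size
    mask <- abs(row_centre - mid) < rep(h_px, each = n_row)
    dim(mask) <- c(n_row, n_col)
    f <- frames[, , i]
    f[mask] <- geom$foreground_level
    frames[, , i] <- f
  }
  if (geom$noise_sd > 0) {
    noise_seed <- (schedule$params$seed + 1000003L) %% .Machine$integer.max
    with_seed(noise_seed, {
      frames <- frames + stats::rnorm(length(frames), sd = geom$noise_sd)
    })
    frames[frames < 0] <- 0
    frames[frames > 255] <- 255
  }
  frame_stack(frames, fps = geom$fps, pixel_size = geom$pixel_size,
              origin_mm = geom$fov_offset)
}

#' Simulate a peristaltic heart video with ground truth
#'
#' Convenience wrapper: builds the schedule, renders the frames and returns
#' both together with a ground-truth record (onset times, realized pause
#' gaps, all parameters and the seed) for parameter-recovery testing.
#'
#' @param schedule Either a [schedule_params()] or a prebuilt
#'   `heart_schedule`.
#' @param waveform A [waveform_params()].
#' @param geom A [tube_geometry()].
#' @return List with elements `stack` (a `frame_stack`), `schedule` and
#'   `truth` (class `heart_truth`).
#' @export
simulate_heart <- function(schedule = schedule_params(),
                           waveform = waveform_params(),
                           geom = tube_geometry()) {
  if (inherits(schedule, "schedule_params")) schedule <- build_schedule(schedule)
  stopifnot(inherits(schedule, "heart_schedule"))
  if (abs(geom$r_min / geom$r_max - waveform$amplitude_ratio) > 1e-6)
    warning("waveform amplitude_ratio differs from geometry r_min/r_max; ",
            "the geometry radii define the rendered span")
  wfsup <- waveform$d1 + waveform$d2 + waveform$d3
  if (wfsup > schedule$params$ibi)
    stop("waveform support d1 + d2 + d3 must not exceed the inter-beat ",
         "interval", call. = FALSE)
  stack <- render_frames(schedule, waveform, geom)
  truth <- structure(list(
    beat_onset_times = schedule$onsets,
    pause_gap_durations = schedule$pause_gaps,
    pause_after = schedule$pause_after,
    wave_speed = geom$wave_speed,
    seed = schedule$params$seed,
    schedule_params = unclass(schedule$params),
    waveform_params = unclass(waveform),
    tube_geometry = unclass(geom)), class = "heart_truth")
  list(stack = stack, schedule = schedule, truth = truth)
}
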