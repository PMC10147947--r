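# Shared fixtures, built in code. Sizes are kept small; the acceptance tests
# run the full-length study conditions.

# Narrow mid-tube imaging window used throughout the unit tests.
test_geom <- function(...) {
  args <- utils::modifyList(list(fov_offset = 8, fov_length = 2), list(...))
  do.call(tube_geometry, args)
}

# Short periodic recording (no pauses), cached across tests.
periodic_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_heart(
        schedule_params(ibi = 1.6, beats_per_burst = Inf, duration = 40),
        geom = test_geom())
    cache
  }
})

# Short intermittent recording with fixed 3.4-s pause gaps.
intermittent_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_heart(
        schedule_params(ibi = 1.519, beats_per_burst = c(8, 9),
                        pause_model = pause_fixed(3.4), duration = 120),
        geom = test_geom())
    cache
  }
})

mid_roi <- function(stack, width_mm = 0.5) roi_for_segment(stack, 9, width_mm)

# Wrap a precomputed signal as a contraction_trace (smoothed = signal) so the
# beat-dynamics operations can be driven with analytic waveforms.
make_trace <- function(y, fps, raw = y) {
  n <- length(y)
  out <- data.frame(frame = seq_len(n) - 1L, time = (seq_len(n) - 1L) / fps,
                    raw = raw, normalized = y, smoothed = y)
  attr(out, "fps") <- fps
  attr(out, "window") <- 1L
  attr(out, "roi") <- roi_rect(0, 0, 1, 1)
  attr(out, "threshold_used") <- NA_real_
  class(out) <- c("contraction_trace", "data.frame")
  out
}

# Periodic trapezoidal area trace built directly from the contraction
# waveform: 1 at maximum expansion, 0 at the contraction-peak plateau.
trapezoid_trace <- function(ibi = 1.6, d1 = 0.35, d2 = 0.15, d3 = 0.70,
                            fps = 100, duration = 20, t0 = 0.8) {
  t <- seq(0, duration, by = 1 / fps)
  s <- (t - t0) %% ibi
  w <- numeric(length(s))
  w[s >= 0 & s < d1] <- s[s >= 0 & s < d1] / d1
  w[s >= d1 & s < d1 + d2] <- 1
  dn <- s >= d1 + d2 & s < d1 + d2 + d3
  w[dn] <- (d1 + d2 + d3 - s[dn]) / d3
  # round away float wobble from the modulo so plateaus are exactly flat
  make_trace(round(1 - w, 9), fps)
}

# Onsets whose contraction trough is safely interior to the recording (the
# last beat or two of a recording can end within half a smoothing window of
# the trace end, where no interior minimum exists).
detectable_troughs <- function(truth, x_roi_mm, margin_s = 1) {
  wf <- truth$waveform_params
  gt <- truth$beat_onset_times + x_roi_mm / truth$wave_speed +
    wf$d1 + wf$d2 / 2
  dur <- truth$schedule_params$duration
  c(lower = sum(gt < dur - margin_s), upper = sum(gt < dur))
}

# Independent brute-force trough detector used as an oracle: enumerates flat
# runs, keeps interior minima (leftmost sample), computes prominence by
# direct max/min scans, filters by prominence.
brute_troughs <- function(y, prominence) {
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (q in seq_len(k)) {
    if (q == 1 || q == k) next
    if (r$values[q - 1] > r$values[q] && r$values[q + 1] > r$values[q]) {
      i <- starts[q]
      below_l <- which(y[seq_len(i - 1)] < y[i])
      jL <- if (length(below_l)) max(below_l) else 1L
      wall_l <- max(y[jL:i])
      after <- seq(i + 1, length(y))
      below_r <- after[y[after] < y[i]]
      jR <- if (length(below_r)) min(below_r) else length(y)
      wall_r <- max(y[i:jR])
      if (min(wall_l, wall_r) - y[i] >= prominence) out <- c(out, i)
    }
  }
  out
}
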