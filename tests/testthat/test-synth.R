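# Synthetic generator: schedule, radius field, rendering.

test_that("purely periodic schedule lays out onsets at the inter-beat interval", {
  sch <- build_schedule(schedule_params(ibi = 1.6, beats_per_burst = Inf,
                                        duration = 8))
  expect_equal(sch$onsets, c(0, 1.6, 3.2, 4.8, 6.4))
  expect_length(sch$pause_gaps, 0)
})

test_that("long-run beat rate of alternating 8/9-beat bursts matches the closed form", {
  sch <- build_schedule(schedule_params(ibi = 1.519, beats_per_burst = c(8, 9),
                                        pause_model = pause_fixed(3.4),
                                        duration = 600))
  # closed form: 8.5 beats per (7.5 * 1.519 + 3.4) seconds
  expected <- 60 * 8.5 / (7.5 * 1.519 + 3.4)
  n <- length(sch$onsets)
  realized <- 60 * (n - 1) / (sch$onsets[n] - sch$onsets[1])
  expect_lt(abs(realized - expected), 0.15)   # edge effects only
  # every logged pause gap equals the fixed 3.4 s
  expect_true(all(sch$pause_gaps == 3.4))
  # gaps between consecutive onsets are the ibi or a logged pause gap
  expect_true(all(abs(diff(sch$onsets) - 1.519) < 1e-9 |
                  abs(diff(sch$onsets) - 3.4) < 1e-9))
  # bursts alternate 8 and 9 beats (interior bursts)
  runs <- diff(c(0, sch$pause_after))
  expect_true(all(runs[seq(1, length(runs), 2)] == 8))
  expect_true(all(runs[seq(2, length(runs), 2)] == 9))
})

test_that("schedules are deterministic given the seed and onsets stay increasing", {
  p <- schedule_params(ibi = 1.5, beats_per_burst = 5,
                       pause_model = pause_lognormal(3.4, 2.1, floor = 2),
                       duration = 200, seed = 11L)
  a <- build_schedule(p)
  b <- build_schedule(p)
  expect_identical(a, b)
  expect_true(all(diff(a$onsets) > 0))
  expect_true(all(a$pause_gaps >= 2))
  c2 <- build_schedule(schedule_params(ibi = 1.5, beats_per_burst = 5,
                                       pause_model = pause_lognormal(3.4, 2.1,
                                                                     floor = 2),
                                       duration = 200, seed = 12L))
  expect_false(identical(a$pause_gaps, c2$pause_gaps))
})

test_that("a schedule too short for one burst is rejected", {
  expect_error(build_schedule(schedule_params(ibi = 1.5, beats_per_burst = 10,
                                              pause_model = pause_fixed(3.4),
                                              duration = 5)),
               "degenerate schedule")
})

test_that("radius field is resting before the first onset and r_min at the peak", {
  sch <- build_schedule(schedule_params(ibi = 1.6, beats_per_burst = Inf,
                                        duration = 20))
  wf <- waveform_params()
  g <- tube_geometry()
  x <- seq(0, 18, by = 1.5)
  expect_true(all(radius_field(sch, wf, g, x, -0.5) == g$r_max))
  # far end contracts only after the wave arrives
  expect_equal(radius_field(sch, wf, g, 18, 0.1), g$r_max)
  # peak of the first beat at x: onset + travel + d1 (+ plateau)
  t_peak <- 0 + 1.5 / g$wave_speed + wf$d1 + wf$d2 / 2
  expect_equal(radius_field(sch, wf, g, 1.5, t_peak), g$r_min)
  expect_equal(g$r_min / g$r_max, 0.5)
  expect_error(radius_field(sch, wf, g, 19, 1), "out of range")
})

test_that("the contraction wave delays distal positions by x / wave_speed", {
  sch <- build_schedule(schedule_params(ibi = 1.6, beats_per_burst = Inf,
                                        duration = 20))
  wf <- waveform_params()
  g <- tube_geometry(wave_speed = 8.9286)
  lag <- programmed_lag(g, 0, 1.5)
  expect_equal(lag, 1.5 / 8.9286)
  expect_equal(lag, 0.168, tolerance = 1e-3)
  tt <- seq(2, 10, by = 0.01)
  r0 <- radius_field(sch, wf, g, 0, tt)
  r15 <- radius_field(sch, wf, g, 1.5, tt + lag)
  expect_equal(r15, r0)
  # monotonicity: faster wave => smaller programmed lag
  speeds <- c(4, 8.93, 20)
  lags <- vapply(speeds, function(v)
    programmed_lag(tube_geometry(wave_speed = v), 0, 1.5), numeric(1))
  expect_true(all(diff(lags) < 0))
})

test_that("a beatless render is a constant band of width 2 r_max / pixel_size", {
  quiet <- structure(list(onsets = numeric(0), pause_gaps = numeric(0),
                          pause_after = integer(0),
                          params = schedule_params(duration = 10)),
                     class = "heart_schedule")
  g <- test_geom()
  st <- render_frames(quiet, waveform_params(), g)
  f1 <- st$frames[, , 1]
  expect_true(all(apply(st$frames, 3, identical, f1)))
  expect_true(all(colSums(f1 > 128) == 2 * g$r_max / g$pixel_size))
})

test_that("noise-free pixel counts match the analytic band area within 1 px per column", {
  sim <- periodic_sim()
  g <- test_geom()
  st <- sim$stack
  px_mm <- g$pixel_size / 1000
  x_mm <- g$fov_offset + (seq_len(dim(st$frames)[2]) - 0.5) * px_mm
  sch <- sim$schedule
  for (i in c(10, 100, 500)) {
    t <- (i - 1) / g$fps
    r <- radius_field(sch, waveform_params(), g, x_mm, t)
    analytic <- 2 * r / g$pixel_size
    counts <- colSums(st$frames[, , i] > 128)
    expect_true(all(abs(counts - analytic) <= 1))
  }
})

test_that("full-systole to full-diastole ROI count ratio equals the amplitude ratio", {
  sim <- periodic_sim()
  roi <- mid_roi(sim$stack)
  th <- threshold_frames(sim$stack)
  counts <- count_foreground(th$binary, roi)
  expect_equal(min(counts) / max(counts), 0.5)
})

test_that("rendering is bit-identical under a fixed seed, including noise", {
  p <- schedule_params(ibi = 1.6, beats_per_burst = 4,
                       pause_model = pause_lognormal(3.4, 2.1, floor = 2),
                       duration = 10, seed = 7L)
  g <- test_geom(noise_sd = 6)
  a <- simulate_heart(p, geom = g)
  b <- simulate_heart(p, geom = g)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$beat_onset_times, b$truth$beat_onset_times)
})

test_that("every scheduled beat whose waveform intersects the recording is rendered", {
  sim <- periodic_sim()
  g <- sim$truth$tube_geometry
  roi <- mid_roi(sim$stack)
  counts <- count_foreground(threshold_frames(sim$stack)$binary, roi)
  # number of distinct dips below diastole = number of scheduled onsets whose
  # (delayed) waveform support intersects the recording at the ROI
  dips <- rle(counts < max(counts))
  n_rendered <- sum(dips$values)
  x_roi <- 9  # ROI centre, mm
  delay <- x_roi / g$wave_speed
  dur <- sim$schedule$params$duration
  support <- waveform_params()
  n_expected <- sum(sim$truth$beat_onset_times + delay < dur)
  expect_equal(n_rendered, n_expected)
})

test_that("geometry rejects an image too small for the dilated tube", {
  expect_error(tube_geometry(height_px = 4), "too small")
  g <- test_geom()
  g$height_px <- 4L
  sch <- build_schedule(schedule_params(ibi = 1.6, beats_per_burst = Inf,
                                        duration = 5))
  expect_error(render_frames(sch, waveform_params(), g), "too small")
})

test_that("waveform and schedule parameter invariants are enforced", {
  expect_error(waveform_params(d1 = 0.7, d3 = 0.35), "d1 must be smaller")
  expect_error(waveform_params(amplitude_ratio = 1.2), "amplitude_ratio")
  expect_error(schedule_params(ibi = 2, duration = 5), "duration")
  expect_error(schedule_params(pause_model = pause_fixed(1)), "floor")
  sch <- build_schedule(schedule_params(ibi = 1.6, beats_per_burst = Inf,
                                        duration = 8))
  expect_error(simulate_heart(sch, waveform_params(d1 = 0.5, d2 = 0.5,
                                                   d3 = 0.8),
                              test_geom()),
               "support")
})
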