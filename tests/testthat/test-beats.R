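# Beat dynamics: trough detection, pause classification, rates, overlay,
# phase segmentation.

test_that("troughs of a pure cosine arrive every period", {
  fps <- 24
  t <- seq(0, 30, by = 1 / fps)
  tr <- make_trace(0.5 + 0.5 * cos(2 * pi * t / 1.6), fps)
  tab <- detect_troughs(tr)
  expect_equal(diff(tab$trough_times), rep(1.6, length(tab$ibis)),
               tolerance = 0.03)
  st <- beat_stats(tab)
  expect_equal(st$mean_cycle, 1.6, tolerance = 0.01)
  expect_equal(st$overall_rate, 37.5, tolerance = 0.2)
})

test_that("detection matches a brute-force prominence oracle on short traces", {
  fps <- 20
  set.seed(9)
  for (rep in 1:5) {
    t <- seq(0, 20, by = 1 / fps)
    y <- 0.5 + 0.3 * cos(2 * pi * t / 1.7) + 0.15 * cos(2 * pi * t / 0.9 + rep)
    y <- round(normalize01(y), 6)
    tr <- make_trace(y, fps)
    tab <- detect_troughs(tr, prominence = 0.2, min_separation = 0)
    expect_equal(tab$trough_indices, brute_troughs(y, 0.2))
  }
})

test_that("detection agrees with the reference peak finder on a clean rhythm", {
  fps <- 24
  t <- seq(0, 40, by = 1 / fps)
  y <- 0.5 + 0.5 * cos(2 * pi * t / 1.6)
  tr <- make_trace(y, fps)
  tab <- detect_troughs(tr)
  ref <- pracma::findpeaks(-y, minpeakheight = -0.2,
                           minpeakdistance = round(0.5 * fps))
  expect_equal(length(tab$trough_times), nrow(ref))
  expect_equal(sort(tab$trough_indices), sort(ref[, 2]), tolerance = 1)
})

test_that("flat minima resolve to the leftmost sample and sparse traces error", {
  y <- c(1, 1, 0.2, 0.2, 0.2, 1, 1, 0.1, 0.1, 1)
  tr <- make_trace(y, fps = 2)
  tab <- detect_troughs(tr, prominence = 0.5, min_separation = 0)
  expect_equal(tab$trough_indices, c(3L, 8L))
  expect_error(detect_troughs(make_trace(c(1, 0, 1, 1, 1, 1), fps = 2),
                              prominence = 0.5, min_separation = 0),
               "insufficient beats")
})

test_that("pause gaps are flagged against the median interval", {
  tab <- structure(list(trough_times = cumsum(c(0, 1.5, 1.5, 3.4, 1.5)),
                        trough_indices = 1:5,
                        ibis = c(1.5, 1.5, 3.4, 1.5),
                        is_pause_gap = rep(NA, 4),
                        burst_id = rep(NA_integer_, 5), fps = 24),
                   class = "beat_table")
  out <- classify_pauses(tab)
  expect_equal(out$is_pause_gap, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$burst_id, c(1L, 1L, 1L, 2L, 2L))
  # periodic trace: no flags
  fps <- 24
  t <- seq(0, 20, by = 1 / fps)
  tab2 <- detect_troughs(make_trace(0.5 + 0.5 * cos(2 * pi * t / 1.6), fps))
  expect_false(any(classify_pauses(tab2)$is_pause_gap))
  # all intervals pausing is pathological
  bad <- tab
  bad$ibis <- c(10, 40, 90, 200)
  expect_error(classify_pauses(bad, kappa = 0.01), "pathological")
})

test_that("flagged gaps on an intermittent synthetic match the programmed gaps exactly", {
  sim <- intermittent_sim()
  tr <- extract_trace(sim$stack, mid_roi(sim$stack))
  fit <- analyze_beats(tr)
  # every interior scheduled beat is detected, one trough per contraction
  rng <- detectable_troughs(sim$truth, x_roi_mm = 9)
  expect_gte(fit$stats$n_beats, rng["lower"])
  expect_lte(fit$stats$n_beats, rng["upper"])
  # gap positions: flagged intervals sit exactly at the programmed burst
  # boundaries (up to beats truncated at the recording end)
  expected_gaps <- sim$truth$pause_after[
    sim$truth$pause_after + 1 <= fit$stats$n_beats]
  expect_equal(which(fit$table$is_pause_gap), expected_gaps)
  expect_equal(fit$stats$n_pauses, length(expected_gaps))
  expect_equal(fit$stats$pause_mean, 3.4, tolerance = 0.05)
})

test_that("rate statistics follow their definitions", {
  tt <- seq(0, by = 1.6, length.out = 11)
  tab <- structure(list(trough_times = tt, trough_indices = seq_along(tt),
                        ibis = diff(tt), is_pause_gap = rep(FALSE, 10),
                        burst_id = rep(1L, 11), fps = 24),
                   class = "beat_table")
  st <- beat_stats(tab)
  expect_equal(st$mean_cycle, 1.6)
  expect_equal(st$overall_rate, 37.5)
  expect_equal(st$burst_rate, 37.5)
  expect_true(is.na(st$pause_mean))
  # closed-form schedule arithmetic: alternating 8/9-beat bursts
  sim <- intermittent_sim()
  tr <- extract_trace(sim$stack, mid_roi(sim$stack))
  st2 <- analyze_beats(tr)$stats
  expect_equal(st2$burst_rate, 60 / 1.519, tolerance = 0.01)
  expect_equal(st2$overall_rate, 60 * 8.5 / (7.5 * 1.519 + 3.4),
               tolerance = 0.25)
  expect_equal(st2$pause_mean, 3.4, tolerance = 0.05)
  expect_lt(st2$pause_sd, 0.05)
  expect_gte(st2$burst_rate, st2$overall_rate)
})

test_that("statistics are invariant to renormalization and constant offsets", {
  sim <- intermittent_sim()
  tr <- extract_trace(sim$stack, mid_roi(sim$stack))
  st <- analyze_beats(tr)$stats
  tr2 <- tr
  tr2$smoothed <- 0.25 + 0.5 * tr$smoothed   # affine rescale
  st2 <- analyze_beats(tr2, prominence = 0.1)$stats
  # invariant up to frame resolution: rescaling can merge float-equal
  # neighbours and move a flat-trough index by one sample
  expect_equal(st2$n_beats, st$n_beats)
  expect_equal(st2$n_pauses, st$n_pauses)
  expect_equal(st2$mean_cycle, st$mean_cycle, tolerance = 1 / 24)
  expect_equal(st2$overall_rate, st$overall_rate, tolerance = 0.05)
})

test_that("overlaying identical beats reproduces a single beat", {
  tr <- trapezoid_trace(fps = 100, duration = 30)
  tab <- classify_pauses(detect_troughs(tr))
  prof <- overlay_beats(tr, tab)
  expect_gt(prof$n_beats, 10)
  expect_equal(apply(prof$segments, 2, stats::var), rep(0, ncol(prof$segments)),
               tolerance = 1e-20)
  expect_equal(prof$mean, prof$segments[1, ])
})

test_that("averaging noisy beats shrinks the deviation like 1/sqrt(n)", {
  set.seed(14)
  fps <- 50
  base <- trapezoid_trace(fps = fps, duration = 80)
  noisy <- base
  noisy$smoothed <- base$smoothed + rnorm(nrow(base), sd = 0.05)
  tab <- detect_troughs(base)          # alignment from the clean trace
  tab$is_pause_gap <- rep(FALSE, length(tab$ibis))
  prof_clean <- overlay_beats(base, tab)
  prof_noisy <- overlay_beats(noisy, tab)
  resid <- prof_noisy$mean - prof_clean$mean
  expect_equal(sd(resid), 0.05 / sqrt(prof_noisy$n_beats), tolerance = 0.35)
})

test_that("phase segmentation recovers trapezoid durations within one grid step", {
  fps <- 100
  tr <- trapezoid_trace(d1 = 0.35, d2 = 0.15, d3 = 0.70, fps = fps,
                        duration = 30)
  tab <- classify_pauses(detect_troughs(tr))
  prof <- segment_phases(overlay_beats(tr, tab))
  d <- prof$phases$durations
  expect_lt(abs(d[["I"]] - 0.35), 1 / fps)
  expect_lt(abs(d[["II"]] - 0.15), 1 / fps)
  expect_lt(abs(d[["III"]] - 0.70), 1 / fps)
  expect_equal(d[["IV"]], 1.6 - 1.2, tolerance = 2 / fps)
  # contraction shorter and steeper than expansion
  expect_lt(d[["I"]], d[["III"]])
  expect_gt(abs(prof$phases$slopes[["I"]]), abs(prof$phases$slopes[["III"]]))
  expect_equal(abs(prof$phases$slopes[["I"]]), 1 / 0.35, tolerance = 0.02)
})

test_that("the four-phase asymmetry survives the full imaging pipeline", {
  sim <- periodic_sim()
  tr <- extract_trace(sim$stack, mid_roi(sim$stack), window = 5)
  tab <- classify_pauses(detect_troughs(tr))
  prof <- segment_phases(overlay_beats(tr, tab), epsilon = 0.05)
  expect_lt(prof$phases$durations[["I"]], prof$phases$durations[["III"]])
  expect_gt(abs(prof$phases$slopes[["I"]]), abs(prof$phases$slopes[["III"]]))
})

test_that("a symmetric triangle wave yields equal contraction and expansion phases", {
  fps <- 100
  t <- seq(-1, 1.5, by = 1 / fps)
  y <- pmin(1, abs(((t + 1) %% 2) - 1))
  prof <- structure(list(offset = t, mean = y, cycle = 2, fps = fps),
                    class = "phase_profile")
  out <- segment_phases(prof)
  d <- out$phases$durations
  expect_equal(d[["I"]], d[["III"]], tolerance = 1 / fps)
  expect_equal(abs(out$phases$slopes[["I"]]), abs(out$phases$slopes[["III"]]),
               tolerance = 0.02)
})

test_that("non-unimodal profiles are rejected", {
  fps <- 50
  t <- seq(-0.8, 1.2, by = 1 / fps)
  y <- 0.5 + 0.5 * cos(2 * pi * t / 0.7)   # several minima in the window
  prof <- structure(list(offset = t, mean = normalize01(y), cycle = 0.7,
                         fps = fps), class = "phase_profile")
  expect_error(segment_phases(prof), "ambiguous phases")
})

test_that("beat_fit methods expose the fitted quantities", {
  sim <- intermittent_sim()
  tr <- extract_trace(sim$stack, mid_roi(sim$stack))
  fit <- analyze_beats(tr)
  co <- coef(fit)
  expect_named(co, c("mean_cycle", "overall_rate", "burst_rate",
                     "pause_mean", "pause_sd"))
  expect_equal(unname(co["burst_rate"]), fit$stats$burst_rate)
  s <- summary(fit)
  expect_s3_class(s, "summary.beat_fit")
  expect_equal(s$n_bursts, fit$stats$n_pauses + 1L)
  expect_output(print(fit), "Beat fit")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
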