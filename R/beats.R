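# Beat dynamics: trough detection on the smoothed area trace, burst/pause
# classification, rate statistics, beat overlay and four-phase segmentation.
# On an area trace the systole is the minimum, so one trough = one beat.

# Local minima of y, leftmost sample of any flat run, interior only.
local_minima <- function(y) {
  dy <- diff(y)
  nz <- which(dy != 0)
  if (length(nz) < 2) return(integer(0))
  s <- sign(dy[nz])
  turn <- which(s[-length(s)] < 0 & s[-1] > 0)
  nz[turn] + 1L            # leftmost sample of the trough (flat) run
}

# Topographic prominence of trough i of y: depth below the lower of the two
# highest points reachable before meeting a deeper trough (or the trace end)
# on each side.
trough_prominence <- function(y, i) {
  n <- length(y)
  left_max <- y[i]
  j <- i - 1L
  while (j >= 1L && y[j] >= y[i]) {
    if (y[j] > left_max) left_max <- y[j]
    j <- j - 1L
  }
  if (j >= 1L) {                      # met a deeper trough: wall capped there
    left_max <- max(y[j:i])
  } else left_max <- max(y[1:i])
  right_max <- y[i]
  j <- i + 1L
  while (j <= n && y[j] >= y[i]) {
    if (y[j] > right_max) right_max <- y[j]
    j <- j + 1L
  }
  if (j <= n) right_max <- max(y[i:j]) else right_max <- max(y[i:n])
  min(left_max, right_max) - y[i]
}

#' Detect contraction troughs
#'
#' Finds local minima of the smoothed trace with at least the given
#' topographic prominence and minimum separation; each trough marks one
#' systole. For flat minima the leftmost sample of the run is taken. When two
#' candidates fall within `min_separation`, the more prominent one wins.
#'
#' @param trace A `contraction_trace` from [extract_trace()] (the `smoothed`
#'   column is analysed).
#' @param prominence Minimum prominence on the normalized scale (default 0.2).
#' @param min_separation Minimum trough spacing, seconds (default 0.5).
#' @return A `beat_table`: list with `trough_times`, `trough_indices`
#'   (1-based samples), `ibis` (successive trough-time differences),
#'   `is_pause_gap` (filled by [classify_pauses()]), `burst_id` and `fps`.
#' @export
detect_troughs <- function(trace, prominence = 0.2, min_separation = 0.5) {
  stopifnot(inherits(trace, "contraction_trace"))
  y <- trace$smoothed
  fps <- attr(trace, "fps")
  cand <- local_minima(y)
  if (length(cand)) {
    prom <- vapply(cand, function(i) trough_prominence(y, i), numeric(1))
    cand <- cand[prom >= prominence]
    prom <- prom[prom >= prominence]
  }
  if (length(cand) > 1) {             # enforce separation, deepest first
    keep <- logical(length(cand))
    for (o in order(-prom)) {
      ti <- trace$time[cand[o]]
      if (!any(keep & abs(trace$time[cand] - ti) < min_separation))
        keep[o] <- TRUE
    }
    cand <- sort(cand[keep])
  }
  if (length(cand) < 2)
    stop("insufficient beats: fewer than 2 troughs detected", call. = FALSE)
  tt <- trace$time[cand]
  structure(list(trough_times = tt, trough_indices = cand,
                 ibis = diff(tt),
                 is_pause_gap = rep(NA, length(tt) - 1L),
                 burst_id = rep(NA_integer_, length(tt)),
                 fps = fps,
                 prominence = prominence, min_separation = min_separation),
            class = "beat_table")
}

#' @export
print.beat_table <- function(x, ...) {
  cat(sprintf("beat_table: %d troughs, %d intervals", length(x$trough_times),
              length(x$ibis)))
  if (!anyNA(x$is_pause_gap))
    cat(sprintf(", %d pause gaps", sum(x$is_pause_gap)))
  cat("\n")
  invisible(x)
}

#' Classify pause gaps and assign burst ids
#'
#' An inter-beat interval is flagged as a pause gap when it exceeds
#' `kappa * median(ibi)`; troughs between consecutive pause gaps share a
#' burst id. The default `kappa = 1.75` sits between the typical
#' pause-to-beat interval ratio (about 2.2 in intermittent hearts) and 1,
#' with margin on both sides.
#'
#' @param table A `beat_table` with at least 3 intervals.
#' @param kappa Pause threshold as a multiple of the median interval.
#' @return The `beat_table` with `is_pause_gap` and `burst_id` filled.
#' @export
classify_pauses <- function(table, kappa = 1.75) {
  stopifnot(inherits(table, "beat_table"))
  if (length(table$ibis) < 3)
    stop("need at least 3 inter-beat intervals", call. = FALSE)
  med <- stats::median(table$ibis)
  flag <- table$ibis > kappa * med
  if (all(flag))
    stop("pathological trace: every interval flagged as a pause",
         call. = FALSE)
  table$is_pause_gap <- flag
  table$burst_id <- cumsum(c(1L, as.integer(flag)))
  table$kappa <- kappa
  table
}

#' Beat-rate and pause statistics
#'
#' Three rate statistics are reported separately because they answer
#' different questions: `mean_cycle` is the mean within-burst inter-beat
#' interval; `overall_rate = 60 * (n - 1) / (t_last - t_first)` counts all
#' beats over the elapsed recording (pauses included) and is unbiased for
#' periodic traces regardless of recording phase; `burst_rate = 60 /
#' mean_cycle` is the rate between pauses. Pause statistics are over the full
#' trough-to-trough durations of flagged gaps.
#'
#' @param table A `beat_table`; if [classify_pauses()] has not been run,
#'   every interval is treated as within-burst.
#' @return A `beat_stats` list: `mean_cycle` (s), `overall_rate` and
#'   `burst_rate` (beats/min), `pause_mean`, `pause_sd` (s; `NA` when there
#'   are no pauses), `n_beats`, `n_pauses`.
#' @export
beat_stats <- function(table) {
  stopifnot(inherits(table, "beat_table"))
  if (length(table$trough_times) < 2)
    stop("insufficient beats", call. = FALSE)
  flag <- table$is_pause_gap
  if (anyNA(flag)) flag <- rep(FALSE, length(table$ibis))
  within <- table$ibis[!flag]
  if (!length(within)) stop("no within-burst intervals", call. = FALSE)
  gaps <- table$ibis[flag]
  tt <- table$trough_times
  structure(list(
    mean_cycle = mean(within),
    overall_rate = 60 * (length(tt) - 1) / (tt[length(tt)] - tt[1]),
    burst_rate = 60 / mean(within),
    pause_mean = if (length(gaps)) mean(gaps) else NA_real_,
    pause_sd = if (length(gaps) > 1) stats::sd(gaps) else
      if (length(gaps) == 1) 0 else NA_real_,
    n_beats = length(tt),
    n_pauses = length(gaps)), class = "beat_stats")
}

#' @export
print.beat_stats <- function(x, ...) {
  cat(sprintf("mean cycle %.3f s | overall rate %.2f /min | burst rate %.2f /min\n",
              x$mean_cycle, x$overall_rate, x$burst_rate))
  if (x$n_pauses > 0)
    cat(sprintf("pauses: n = %d, %.2f +/- %.2f s\n", x$n_pauses,
                x$pause_mean, x$pause_sd))
  else cat("pauses: none\n")
  invisible(x)
}

#' Fit the beat model to a contraction trace
#'
#' One-stop analysis: detects troughs, classifies pauses and bursts, and
#' computes rate statistics. Returns a classed object with `print`,
#' `summary`, `coef` and `plot` methods.
#'
#' @param trace A `contraction_trace`.
#' @param prominence,min_separation Passed to [detect_troughs()].
#' @param kappa Passed to [classify_pauses()]; set `NA` to skip pause
#'   classification (all intervals treated as within-burst).
#' @return An object of class `beat_fit` with elements `table`
#'   (`beat_table`), `stats` (`beat_stats`) and `trace`.
#' @examples
#' sim <- simulate_heart(schedule_params(ibi = 1.6, beats_per_burst = Inf,
#'                                       duration = 30),
#'                       geom = tube_geometry(fov_length = 2,
#'                                            fov_offset = 8))
#' tr <- extract_trace(sim$stack, roi_for_segment(sim$stack, 9, 0.5))
#' fit <- analyze_beats(tr)
#' coef(fit)["mean_cycle"]
#' @export
analyze_beats <- function(trace, prominence = 0.2, min_separation = 0.5,
                          kappa = 1.75) {
  tab <- detect_troughs(trace, prominence, min_separation)
  if (!is.na(kappa) && length(tab$ibis) >= 3)
    tab <- classify_pauses(tab, kappa)
  st <- beat_stats(tab)
  structure(list(table = tab, stats = st, trace = trace),
            class = "beat_fit")
}

#' @export
print.beat_fit <- function(x, ...) {
  cat(sprintf("Beat fit: %d beats over %.1f s\n", x$stats$n_beats,
              diff(range(x$table$trough_times))))
  print(x$stats)
  invisible(x)
}

#' @export
summary.beat_fit <- function(object, ...) {
  s <- object$stats
  tab <- object$table
  flag <- tab$is_pause_gap
  if (anyNA(flag)) flag <- rep(FALSE, length(tab$ibis))
  out <- list(stats = s,
              n_bursts = if (length(tab$burst_id) && !anyNA(tab$burst_id))
                max(tab$burst_id) else 1L,
              ibi_quartiles = stats::quantile(tab$ibis[!flag],
                                              c(0.25, 0.5, 0.75)),
              pause_gaps = tab$ibis[flag])
  class(out) <- "summary.beat_fit"
  out
}

#' @export
print.summary.beat_fit <- function(x, ...) {
  print(x$stats)
  cat(sprintf("bursts: %d | within-burst ibi quartiles: %.3f / %.3f / %.3f s\n",
              x$n_bursts, x$ibi_quartiles[1], x$ibi_quartiles[2],
              x$ibi_quartiles[3]))
  invisible(x)
}

#' @export
coef.beat_fit <- function(object, ...) {
  s <- object$stats
  c(mean_cycle = s$mean_cycle, overall_rate = s$overall_rate,
    burst_rate = s$burst_rate, pause_mean = s$pause_mean,
    pause_sd = s$pause_sd)
}

#' @export
plot.beat_fit <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$time, tr$smoothed, type = "l",
                 xlab = "time (s)", ylab = "normalized area (smoothed)", ...)
  graphics::points(x$table$trough_times,
                   tr$smoothed[x$table$trough_indices],
                   col = "firebrick", pch = 19, cex = 0.6)
  flag <- x$table$is_pause_gap
  if (!anyNA(flag) && any(flag)) {
    i <- which(flag)
    graphics::segments(x$table$trough_times[i], 1.02,
                       x$table$trough_times[i + 1], 1.02,
                       col = "steelblue", lwd = 3)
  }
  invisible(x)
}

#' Overlay successive beats into a mean cycle profile
#'
#' Cuts a segment `[trough - span_before * m, trough + span_after * m]`
#' (where `m` is the median within-burst interval) around every detected
#' trough, aligns the segments at the trough, resamples them on a common grid
#' at the trace's frame interval and averages pointwise. Segments that would
#' extend beyond the trace are dropped.
#'
#' @param trace A `contraction_trace`.
#' @param table A `beat_table` for that trace.
#' @param span_before,span_after Segment extent as fractions of the median
#'   within-burst interval.
#' @return A `phase_profile`: list with `offset` (s, 0 at the trough),
#'   `mean`, `sd`, `segments` (beat x grid matrix), `n_beats`, `cycle`
#'   (median within-burst interval) and `fps`.
#' @export
overlay_beats <- function(trace, table, span_before = 0.5,
                          span_after = 0.75) {
  stopifnot(inherits(trace, "contraction_trace"),
            inherits(table, "beat_table"))
  flag <- table$is_pause_gap
  if (anyNA(flag)) flag <- rep(FALSE, length(table$ibis))
  m <- stats::median(table$ibis[!flag])
  fps <- attr(trace, "fps")
  offset <- seq(-span_before * m, span_after * m, by = 1 / fps)
  tmin <- min(trace$time); tmax <- max(trace$time)
  segs <- lapply(table$trough_times, function(tt) {
    if (tt + offset[1] < tmin || tt + offset[length(offset)] > tmax)
      return(NULL)
    stats::approx(trace$time, trace$smoothed, xout = tt + offset)$y
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) < 3)
    stop("fewer than 3 complete beat segments available", call. = FALSE)
  mat <- do.call(rbind, segs)
  structure(list(offset = offset, mean = colMeans(mat),
                 sd = apply(mat, 2, stats::sd), segments = mat,
                 n_beats = nrow(mat), cycle = m, fps = fps),
            class = "phase_profile")
}

#' @export
print.phase_profile <- function(x, ...) {
  cat(sprintf("phase_profile: %d beats overlaid on %d grid points (%.2f s cycle)\n",
              x$n_beats, length(x$offset), x$cycle))
  if (!is.null(x$phases)) {
    d <- x$phases$durations
    cat(sprintf("phases I-IV: %.3f / %.3f / %.3f / %.3f s; slopes I %.2f, III %.2f per s\n",
                d[1], d[2], d[3], d[4],
                x$phases$slopes[1], x$phases$slopes[2]))
  }
  invisible(x)
}

#' @export
plot.phase_profile <- function(x, ...) {
  graphics::matplot(x$offset, t(x$segments), type = "l", lty = 1,
                    col = grDevices::grey(0.8),
                    xlab = "time from trough (s)", ylab = "normalized area",
                    ...)
  graphics::lines(x$offset, x$mean, lwd = 2, col = "firebrick")
  invisible(x)
}

#' Segment the mean beat profile into four phases
#'
#' The cycle profile decomposes into contraction (phase I), contraction-peak
#' plateau (phase II), expansion (phase III) and maximum-expansion plateau
#' (phase IV). Samples within `epsilon * range` of the minimum form the
#' phase-II run and samples within `epsilon * range` of the maximum form the
#' phase-IV plateaus. Slopes of phases I and III are least-squares line fits
#' over the samples strictly between those bands. Durations are reported
#' from the intersections of the fitted lines with the plateau levels (the
#' medians of the phase-II and phase-IV runs): on a noise-free trapezoidal
#' cycle this recovers the programmed durations exactly, whereas raw
#' threshold-run lengths would be biased by `epsilon * range / |slope|` at
#' every boundary.
#'
#' @param profile A `phase_profile` from [overlay_beats()], or any list with
#'   numeric `offset` and `mean` of equal length (and optionally `cycle`).
#' @param epsilon Plateau band half-width as a fraction of the profile range.
#' @return The profile with a `phases` element: `durations` (I-IV, seconds;
#'   IV is the cycle remainder, `NA` if the cycle length is unknown),
#'   `slopes` (I and III, 1/s), `boundaries` (times of the four fitted
#'   corners) and `runs` (raw threshold-run index ranges).
#' @export
segment_phases <- function(profile, epsilon = 0.05) {
  y <- profile$mean
  tt <- profile$offset
  stopifnot(length(y) == length(tt), length(y) > 5)
  rng <- max(y) - min(y)
  if (rng <= 0) stop("flat profile", call. = FALSE)
  lo <- y <= min(y) + epsilon * rng
  hi <- y >= max(y) - epsilon * rng

  runs_of <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
  }
  lo_runs <- runs_of(lo)
  if (nrow(lo_runs) != 1)
    stop("ambiguous phases: profile is not unimodal", call. = FALSE)
  ii <- lo_runs[1, ]                       # phase II run
  hi_runs <- runs_of(hi)
  pre <- hi_runs[hi_runs[, "end"] < ii["start"], , drop = FALSE]
  post <- hi_runs[hi_runs[, "start"] > ii["end"], , drop = FALSE]
  if (nrow(pre) == 0 || nrow(post) == 0)
    stop("ambiguous phases: no maximum-expansion plateau on both sides",
         call. = FALSE)
  iv_pre <- pre[nrow(pre), ]
  iv_post <- post[1, ]

  level_lo <- stats::median(y[ii["start"]:ii["end"]])
  level_hi <- stats::median(c(y[iv_pre["start"]:iv_pre["end"]],
                              y[iv_post["start"]:iv_post["end"]]))

  fit_line <- function(from, to) {
    idx <- seq(from, to)
    idx <- idx[y[idx] > min(y) + epsilon * rng & y[idx] < max(y) - epsilon * rng]
    if (length(idx) < 2) idx <- seq(from, to)
    stats::coef(stats::lm(y[idx] ~ tt[idx]))
  }
  c1 <- fit_line(iv_pre["end"], ii["start"])     # phase I (descending)
  c3 <- fit_line(ii["end"], iv_post["start"])    # phase III (ascending)
  b1 <- unname(c1[2]); a1 <- unname(c1[1])
  b3 <- unname(c3[2]); a3 <- unname(c3[1])
  if (!(b1 < 0 && b3 > 0))
    stop("ambiguous phases: could not fit descending/ascending limbs",
         call. = FALSE)
  t_top1 <- (level_hi - a1) / b1
  t_bot1 <- (level_lo - a1) / b1
  t_bot3 <- (level_lo - a3) / b3
  t_top3 <- (level_hi - a3) / b3
  d1 <- t_bot1 - t_top1
  d2 <- t_bot3 - t_bot1
  d3 <- t_top3 - t_bot3
  d4 <- if (!is.null(profile$cycle)) profile$cycle - (d1 + d2 + d3)
        else NA_real_
  profile$phases <- list(
    durations = c(I = d1, II = d2, III = d3, IV = d4),
    slopes = c(I = b1, III = b3),
    boundaries = c(t_top1, t_bot1, t_bot3, t_top3),
    levels = c(low = level_lo, high = level_hi),
    runs = list(II = ii, IV_pre = iv_pre, IV_post = iv_post),
    epsilon = epsilon)
  profile
}
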