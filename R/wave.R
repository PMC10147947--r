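# Peristaltic wave kinematics: lag between two ROI traces and its conversion
# to a wave speed. The reported 24 fps frame period (41.7 ms) is coarser than
# typical lags, so the cross-correlation peak is refined to sub-frame
# resolution by parabolic interpolation.

#' Estimate the contraction lag between two traces
#'
#' With `method = "xcorr"`, computes the mean-removed normalized
#' cross-correlation of the two smoothed traces over integer lags up to half
#' the median inter-beat interval (to avoid aliasing onto the neighbouring
#' beat), then refines the integer-lag peak with a parabola through the peak
#' and its two neighbours. With `method = "trough_match"`, pairs each trough
#' of `trace_a` with the nearest trough of `trace_b` and averages the time
#' differences.
#'
#' Sign convention: `delta_t > 0` means `trace_a` lags `trace_b`
#' (`a(t) ~ b(t - delta_t)`), i.e. the region of `trace_a` contracts later.
#'
#' @param trace_a,trace_b `contraction_trace` objects of equal length and
#'   frame rate, each containing at least 3 beats.
#' @param method `"xcorr"` (default) or `"trough_match"`.
#' @param max_lag Optional search half-window in seconds; defaults to half
#'   the median inter-beat interval of `trace_a`.
#' @return A `lag_estimate`: list with `delta_t` (s), `method`,
#'   `per_beat_lags` (trough_match only), `max_lag` and `fps`.
#' @export
estimate_lag <- function(trace_a, trace_b, method = c("xcorr", "trough_match"),
                         max_lag = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(trace_a, "contraction_trace"),
            inherits(trace_b, "contraction_trace"))
  fps <- attr(trace_a, "fps")
  if (!isTRUE(all.equal(fps, attr(trace_b, "fps"))))
    stop("frame-rate mismatch between traces", call. = FALSE)
  if (nrow(trace_a) != nrow(trace_b))
    stop("traces must have equal length", call. = FALSE)

  tab_a <- detect_troughs(trace_a)
  tab_b <- detect_troughs(trace_b)
  if (length(tab_a$trough_times) < 3 || length(tab_b$trough_times) < 3)
    stop("each trace needs at least 3 beats", call. = FALSE)
  med_ibi <- stats::median(tab_a$ibis)
  if (is.null(max_lag)) max_lag <- med_ibi / 2

  if (method == "trough_match") {
    lags <- vapply(tab_a$trough_times, function(ta) {
      diffs <- ta - tab_b$trough_times
      d <- diffs[which.min(abs(diffs))]
      if (abs(d) <= max_lag) d else NA_real_
    }, numeric(1))
    lags <- lags[!is.na(lags)]
    if (!length(lags)) stop("no matchable troughs within the lag window",
                            call. = FALSE)
    est <- structure(list(delta_t = mean(lags), method = method,
                          per_beat_lags = lags, max_lag = max_lag,
                          fps = fps), class = "lag_estimate")
    return(est)
  }

  a <- trace_a$smoothed - mean(trace_a$smoothed)
  b <- trace_b$smoothed - mean(trace_b$smoothed)
  n <- length(a)
  m <- max(1L, as.integer(floor(max_lag * fps)))
  if (m >= n - 2) stop("lag window too wide for the trace", call. = FALSE)
  lags <- (-m):m
  cc <- vapply(lags, function(L) {
    if (L >= 0) stats::cor(a[(1 + L):n], b[1:(n - L)])
    else stats::cor(a[1:(n + L)], b[(1 - L):n])
  }, numeric(1))
  k <- which.max(cc)
  if (k == 1L || k == length(cc))
    stop("lag out of range: correlation peak at the window boundary",
         call. = FALSE)
  # parabolic sub-frame refinement through the peak and its neighbours
  denom <- cc[k - 1] - 2 * cc[k] + cc[k + 1]
  delta <- if (denom < 0) 0.5 * (cc[k - 1] - cc[k + 1]) / denom else 0
  structure(list(delta_t = (lags[k] + delta) / fps, method = method,
                 per_beat_lags = NULL, max_lag = max_lag, fps = fps,
                 correlation = cc[k]),
            class = "lag_estimate")
}

#' @export
print.lag_estimate <- function(x, ...) {
  cat(sprintf("lag estimate (%s): %.1f ms\n", x$method, 1000 * x$delta_t))
  invisible(x)
}

#' Convert a contraction lag to a peristaltic wave speed
#'
#' `speed = delta_x / |delta_t|`. When the lag was estimated as
#' `estimate_lag(anterior, posterior)`, a positive lag means the anterior
#' region contracts later, i.e. the wave travels anterograde
#' (posterior to anterior).
#'
#' @param delta_x Distance between the two measured regions, mm.
#' @param lag A `lag_estimate` (or a lag in seconds).
#' @param resolution_floor Smallest resolvable `|delta_t|`, seconds; defaults
#'   to a quarter frame period. Below it the regions contract
#'   near-simultaneously and no finite speed can be quoted.
#' @return A `wave_speed` object: `speed` (mm/s), `delta_x`, `delta_t`,
#'   `direction` (`"anterograde"` or `"retrograde"`).
#' @export
wave_speed <- function(delta_x, lag, resolution_floor = NULL) {
  stopifnot(is.numeric(delta_x), delta_x > 0)
  if (inherits(lag, "lag_estimate")) {
    delta_t <- lag$delta_t
    if (is.null(resolution_floor)) resolution_floor <- 1 / (4 * lag$fps)
  } else {
    delta_t <- as.numeric(lag)
    if (is.null(resolution_floor)) resolution_floor <- 1 / (4 * 24)
  }
  if (abs(delta_t) < resolution_floor)
    stop("unresolvable speed: lag below the resolution floor ",
         "(near-simultaneous contraction)", call. = FALSE)
  structure(list(speed = delta_x / abs(delta_t), delta_x = delta_x,
                 delta_t = delta_t,
                 direction = if (delta_t > 0) "anterograde" else "retrograde"),
            class = "wave_speed")
}

#' @export
print.wave_speed <- function(x, ...) {
  cat(sprintf("wave speed: %.2f mm/s (%s; %.1f mm / %.1f ms)\n",
              x$speed, x$direction, x$delta_x, 1000 * abs(x$delta_t)))
  invisible(x)
}
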