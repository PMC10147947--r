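---
title: "Quantifying an intermittent peristaltic heartbeat from video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying an intermittent peristaltic heartbeat from video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hearttrace)
```

## The measurement problem

A tubular invertebrate heart filmed from above appears as a bright band on a
dark background whose width oscillates as the heart contracts. The classic
semi-automated workflow — threshold the video, count white pixels per frame
in a region of interest (ROI), normalize, smooth, and read beats off the
resulting trace — is easy to do once in an image-analysis GUI and a
spreadsheet, but hard to audit or repeat. `hearttrace` reimplements that
workflow as tested code, together with the downstream physiology: burst/pause
structure, the four-phase cycle shape, peristaltic wave speed from a
two-region lag, and the cylindrical-model cardiac indices.

Because real recordings of this preparation are rarely shareable, the package
also contains a synthetic video generator with exact ground truth. Every
analysis stage is validated by parameter recovery against that generator.

## The generator: what it emulates

The generator simulates study-like conditions:

* **Rhythm.** Beats arrive in bursts at a within-burst inter-beat interval
  (IBI), separated by prolonged pauses. Defaults: IBI 1.519 s (= 60 / 39.5,
  the between-pause rate it should reproduce), bursts alternating 8 and 9
  beats, and pause gaps drawn from a lognormal with mean 3.4 s and sd 2.1 s,
  truncated below at 2 s. With these values the long-run overall rate is
  60 · 8.5 / (7.5 · 1.519 + 3.4) ≈ 34.5 beats/min, matching the
  observed coexistence of a ~39.5/min burst rate and a ~34.4/min overall
  rate. A pause is a *full inter-onset gap* — it replaces a beat interval
  rather than extending one — so the logged gap is directly the
  trough-to-trough duration a trace analysis measures.
* **Per-beat waveform.** The radius follows a trapezoid: linear contraction
  over `d1`, a contraction-peak plateau `d2`, linear re-expansion over `d3`,
  and a maximum-expansion plateau for the rest of the cycle. Defaults
  `d1 = 0.35`, `d2 = 0.15`, `d3 = 0.70` s satisfy the qualitative observation
  that contraction is shorter and steeper than expansion (`d1 < d3`); no
  quantitative phase durations have been published, so these are illustrative.
  The trapezoid was chosen over a smooth shape because every downstream
  quantity (band area, phase durations, slopes) then has an exact analytic
  oracle.
* **Peristalsis.** A single anterograde travelling delay: position `x`
  contracts `x / wave_speed` after the posterior end, with no dispersion and
  no amplitude decay — the simplest model consistent with a constant reported
  wave speed. Default 8.9286 mm/s, i.e. exactly 168 ms over 1.5 mm.
* **Geometry and imaging.** End-diastolic radius 80 µm, end-systolic 40 µm
  (diameter halves at systole), tube length 18 mm, 24 frames/s, 20 µm/px.
  The camera images a configurable field of view along the tube, as a real
  recording shows only a few millimetres of the heart. The band is drawn
  hard-edged with the midline on a pixel-row boundary, so an integer
  half-width of `h` pixels rasters to exactly `2h` foreground pixels — the
  systole/diastole count ratio is exactly 0.5 at the defaults, and
  thresholding is exactly invertible. Anti-aliasing is deliberately absent.
* **Noise and determinism.** Optional Gaussian pixel noise (default 0) on an
  RNG substream independent of the schedule substream; one root seed makes
  the frame stack and ground truth bit-reproducible.

What the generator does **not** emulate: uneven illumination, background
debris and motion, focus drift, perspective foreshortening, ostial valve
detail, hemolymph flow, and heartbeat reversals. Passing recovery tests
therefore demonstrate that the *analysis chain* is correct and unbiased under
ideal imaging, not that thresholding will be trouble-free on any real video.

## Trace extraction choices

* **Threshold.** Published workflows typically say only that a binary
  threshold was "adjusted". The default here is Otsu's criterion computed
  once on the pooled histogram of the whole stack. A per-frame threshold was
  rejected because it would modulate counts independently of geometry —
  exactly the signal being measured. A fixed level is available
  (`threshold = 128`), and the level actually used is recorded in the trace
  metadata and the CSV sidecar. On the plateau between two well-separated
  modes the Otsu objective is nearly flat; this implementation returns the
  first maximizing grey level, which different implementations may place
  elsewhere on the plateau with virtually identical masks.
* **Normalization.** Min–max over the entire series, so 0 is the deepest
  systole and 1 the fullest diastole of the recording. Constant traces are a
  hard error ("degenerate trace"), not a silent NaN.
* **Smoothing.** Centred moving average, default window 20 samples
  (0.83 s at 24 fps). For an even window `w` the filter uses the standard
  half-weight form (weights ½, 1, …, 1, ½ over `[i − w/2, i + w/2]`, divided
  by `w`): an asymmetric `[i − 10, i + 9]` window would shift every feature
  by half a sample and bend linear ramps, whereas the symmetric form is
  phase-neutral. At the trace ends the window shrinks to the largest
  symmetric plain mean rather than padding, so no values are fabricated.
  Output is clamped to the input range to guard the convexity invariant
  against floating-point accumulation.
* **ROI convention.** 0-based, half-open `[col0, col0 + width)` rectangles,
  row-major — stated in the docs and in every sidecar file.

## Beat detection and statistics

Troughs (systoles) are local minima of the smoothed trace filtered by
topographic prominence (default 0.2 on the normalized scale) and minimum
separation (0.5 s); for flat minima the leftmost sample is the trough, a
deterministic tie-break. An interval is a pause when it exceeds
κ · median(IBI); κ = 1.75 sits with margin between 1 (a normal beat) and the
typical gap-to-IBI ratio of ≈ 2.2 (3.4 s vs 1.5 s).

Reported cycle statistics deliberately come in three flavours because the
obvious single definition cannot reproduce all published figures at once
(60 / 1.6 s = 37.5/min is neither ~34.4 nor ~39.5):

* `mean_cycle` — mean within-burst IBI;
* `overall_rate` — `60 (n − 1) / (t_last − t_first)` over all troughs,
  pauses included; unbiased for periodic traces regardless of where the
  recording starts;
* `burst_rate` — `60 / mean_cycle`, the rate between pauses.

Pause duration is reported as the full trough-to-trough gap (not the excess
over a normal cycle), consistent with the generator's convention; both
conventions are defensible for real data, and the choice is logged here so
results remain comparable.

## Phase segmentation

Overlaid beats (segments `[trough − 0.5 m, trough + 0.75 m]`, `m` the median
within-burst IBI, linearly resampled at the frame interval and trough-aligned)
are averaged into a cycle profile, then decomposed into four phases. Samples
within ε·range (default ε = 0.05) of the minimum form the phase-II run and
samples within ε·range of the maximum the phase-IV plateaus; phases I and III
are the descending/ascending limbs between them, with least-squares slopes.

Durations are *not* the raw threshold-run lengths: on a trapezoid those are
biased by ε·range/|slope| at every boundary (≈ 35 ms on phase I and ≈ 70 ms
on phase III at the defaults). Instead the fitted lines of phases I and III
are intersected with the plateau levels (medians of the II and IV runs); on a
noise-free trapezoid this recovers the programmed durations exactly, and the
package's tests assert recovery within one grid step. Non-unimodal profiles
(more than one low run) raise "ambiguous phases" rather than guessing.

## Lag and wave speed

The default lag estimator is the mean-removed normalized cross-correlation of
the two smoothed traces over integer lags up to half the median IBI (a wider
window would alias onto the neighbouring beat), with the integer peak refined
by a parabola through the peak and its two neighbours. Sub-frame refinement
is essential at 24 fps: the frame period is 41.7 ms while physiological lags
over 1.5 mm are ~168 ms, not an integer number of frames. A peak on the
window boundary raises "lag out of range". A trough-matching estimator
(nearest-trough pairing, mean difference) is provided as a cross-check; the
two agree within one frame on clean data.

`wave_speed()` refuses lags below a resolution floor (default a quarter frame
period) — near-simultaneous contraction cannot be converted into a finite
speed honestly. Direction is called from the sign convention that
`estimate_lag(anterior, posterior) > 0` means the anterior region lags, i.e.
anterograde propagation.

## Cardiac indices and the printed scale

All internal computation is in mm and mm³. For the default geometry
(r_max = 0.08 mm, r_min = 0.04 mm, l = 18 mm):
EDV = 0.3619 mm³, ESV = 0.0905 mm³, SV = 0.2714 mm³, EF = 0.75 exactly
(r_min = r_max/2 makes ESV = EDV/4).

Published figures for this system quote the volumes ×10³ (a µm³/mm³ unit slip
in the source material: π·(0.08 mm)²·18 mm is 0.362 mm³, not 362 µm³) and
apply sequential rounding — SV from the already-rounded EDV and ESV
(362 − 90.5 = 271.5 → 272), CO from the rounded SV (0.272 · 34.4 = 9.357),
and the circulation time from the 2-significant-figure flow rate
(100 / 9.3 = 10.75 min = 10:45). `cardiac_indices()` reports full-precision
values *and* a `printed` element that reproduces that chain digit for digit,
so both the physically coherent numbers and the quotable ones are available.
Rounding is half-away-from-zero, the convention used in those figures.

`volume_fractions()` counts voxels per label exactly and normalizes over
non-background labels only, since compartment percentages are quoted as
fractions of the circulatory system, not of the bounding box.

## Degenerate inputs and errors

Constant images and constant traces, schedules too short for one burst,
fewer than two detected troughs, all-pause interval sets, profiles without a
unique minimum, zero stroke volume ("no net flow"), and ROIs outside the
frame all raise immediate, specific errors instead of propagating NaNs.
`run_pipeline()` re-raises any stage failure labelled with the stage name.

## Problem sizes and runtime

The bundled validation uses a 2–2.5 mm field of view at 20 µm/px (so a
10-minute, 14 400-frame recording is a ~23-million-pixel stack): recoveries
run in seconds while still exercising hundreds of beats and dozens of pauses.
The acceptance script simulates 5 minutes (periodic), 10 minutes
(intermittent) and 2 minutes (two-ROI lag) and completes in well under a
minute on one CPU.

## Known limitations

* The generator's rendering is ideal (uniform tube brightness, black
  background); robustness of Otsu thresholding to realistic illumination is
  untested here.
* Phase durations of real hearts are only constrained qualitatively
  (`d1 < d3`); absolute recovered durations inherit the smoothing window's
  blur, so compare durations only across traces processed with the same
  window.
* The wave model is a pure delay; if a real contraction wave accelerates or
  decays along the tube, the two-ROI lag yields an average speed between the
  ROIs, and `estimate_lag` assumes the lag is constant across beats.
* Heartbeat reversals (retrograde episodes) are out of scope: the direction
  call assumes one dominant propagation direction per recording.
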