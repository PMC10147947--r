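# hearttrace

Quantification of the intermittent, peristaltic heartbeat of tubular
invertebrate hearts from grayscale time-lapse video.

Many invertebrates — onychophorans (velvet worms) being a striking example —
have a dorsal tubular heart that beats in *bursts*: runs of rhythmic
contractions separated by prolonged pauses, with each contraction travelling
as an anterograde peristaltic wave along the tube. `hearttrace` provides the
full measurement chain for such recordings, for physiologists and
morphologists who film a beating heart under a stereomicroscope and want
reproducible numbers out of the video:

1. **Trace extraction** — binary-threshold the frames (pooled-histogram Otsu
   or a fixed level), count foreground pixels per frame inside a rectangular
   ROI, min–max normalize to [0, 1] and smooth with a centred moving average
   (default window 20 samples). On the resulting area trace the systole is
   the minimum.
2. **Beat dynamics** — detect contraction troughs (prominence- and
   separation-filtered local minima), flag pause gaps
   (interval > κ · median interval, κ = 1.75), and report three rate
   statistics with explicit definitions: mean within-burst cycle
   `mean(IBI_within)`, overall rate `60·(n−1)/(t_last − t_first)` (pauses
   included), and between-pause rate `60 / mean(IBI_within)`. Beats can be
   overlaid, trough-aligned, and segmented into the four phases of the cycle
   — contraction (I), contraction peak (II), expansion (III), maximum
   expansion plateau (IV) — with least-squares slopes for I and III.
3. **Wave kinematics** — estimate the contraction lag between two ROIs by
   mean-removed normalized cross-correlation with parabolic sub-frame
   refinement (a 168 ms lag is not a multiple of the 41.7 ms frame period at
   24 fps, so sub-frame resolution matters), and convert it to a peristaltic
   wave speed `v = Δx / |Δt|` with a direction call (anterograde ⇔ the
   anterior region lags).
4. **Cardiac indices** — from a cylindrical heart model with end-diastolic
   radius r_max, end-systolic radius r_min and length l:

   ```
   EDV = π r_max² l        ESV = π r_min² l       SV = EDV − ESV
   EF  = SV / EDV          CO  = SV · HR
   relative flow rate = (EDV/CV) · EF · HR        [%/min]
   circulation time   = 100% / relative flow rate [min]
   ```

   where EDV/CV is the heart's fraction of the total circulatory volume.
   Voxel morphometry of labelled volumes (`volume_fractions()`) supports the
   CV side.
5. **Synthetic generator** — a peristaltically contracting bright tube on a
   dark background, rendered as a frame stack with a machine-readable
   ground-truth log (onset times, realized pause gaps, programmed lags), so
   the whole pipeline can be validated by parameter recovery.

## Worked example

Simulate two minutes of an intermittent heart (within-burst inter-beat
interval 1.519 s, bursts alternating 8 and 9 beats, fixed 3.4 s pauses),
extract a mid-tube trace, fit the beat model, estimate the wave speed from
two ROIs 1.5 mm apart, and compute cardiac indices from the measured rate:

```r
library(hearttrace)

sim <- simulate_heart(
  schedule_params(ibi = 1.519, beats_per_burst = c(8, 9),
                  pause_model = pause_fixed(3.4), duration = 120, seed = 42),
  waveform_params(),
  tube_geometry(fov_offset = 8, fov_length = 2.5))

trace <- extract_trace(sim$stack, roi_for_segment(sim$stack, 9, 0.5))
fit <- analyze_beats(trace)
fit
#> Beat fit: 68 beats over 115.0 s
#> mean cycle 1.519 s | overall rate 34.97 /min | burst rate 39.51 /min
#> pauses: n = 7, 3.40 +/- 0.02 s

post <- extract_trace(sim$stack, roi_for_segment(sim$stack, 8.5, 0.5))
ant  <- extract_trace(sim$stack, roi_for_segment(sim$stack, 10.0, 0.5))
wave_speed(1.5, estimate_lag(ant, post))
#> wave speed: 8.84 mm/s (anterograde; 1.5 mm / 169.7 ms)

cardiac_indices(cardiac_geometry(0.08, 0.04, 18),
                hr = coef(fit)["overall_rate"],
                heart_volume_fraction = 0.0036)
#> Cardiac indices (cylindrical heart model)
#>   EDV 0.3619 mm^3 | ESV 0.0905 mm^3 | SV 0.2714 mm^3 | EF 75%
#>   HR 35.0 /min | CO 9.4918 mm^3/min
#>   relative flow rate 9.442 %/min | circulation time 10.59 min
#>   printed scale: EDV 362, ESV 90.5, SV 272 | EF 75% | CO 9.512 | 9.4 %/min | 10:38 min
```

Reading: the fit recovered the programmed 1.519 s cycle exactly; the overall
rate (34.97/min) is lower than the between-pause rate (39.51/min) because the
seven detected 3.4-s pauses count against elapsed time; the 1.5-mm ROI
separation and the 169.7 ms estimated lag give an 8.84 mm/s anterograde wave;
and with an 80 µm / 40 µm radius cylinder 18 mm long, three quarters of the
end-diastolic volume is expelled per beat (EF 75%). The "printed scale" line
renders the volumes ×10³ with the sequential-rounding convention described in
`?cardiac_indices`.

`run_pipeline(default_config())` chains all stages (including a ground-truth
recovery section) and can write every intermediate artifact — frames as
multipage TIFF, traces as CSV with a JSON metadata sidecar, ground truth and
report as JSON — to a directory.

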