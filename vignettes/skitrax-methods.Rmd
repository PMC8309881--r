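---
title: "Methods: micro-sensor race analysis for classical cross-country skiing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: micro-sensor race analysis for classical cross-country skiing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skitrax)
```

`skitrax` analyses classical cross-country skiing races recorded with a
body-worn unit combining a 10 Hz GNSS receiver and a 100 Hz tri-axial
accelerometer and gyroscope (z axis frontal). This vignette documents the
models and procedures, every tunable parameter with its default and
rationale, the numerical choices made where the method description is open,
and what the synthetic-data generator does and does not emulate.

## Measurement model and kinematic derivation

Speed is derived by time differentiation of position: fixes are projected
onto a local tangent plane centred on the track's median fix (exact
round-trip; scale error negligible over a 2.5 km loop), and horizontal
speed is the magnitude of the central finite difference of the planar
coordinates, one-sided at the ends, then smoothed with a centred moving
average over `smooth_window_s = 1 s`. One second is short against every
terrain feature (the shortest course segment is 100 m, ≥10 s of skiing) but
long enough to suppress differentiation noise at 10 Hz.

Cumulative distance is the running sum of horizontal step lengths. Because
a sum of noisy steps is biased upward, the pipeline first smooths the
positions themselves over the same 1 s window (`smooth_positions()`);
receiver error at 10 Hz is strongly autocorrelated, so this removes most of
the step-level error without shortening real curvature at skiing speeds.

IMU samples are trimmed to the GNSS time span and each sample carries a
linearly interpolated speed and cumulative distance.

## Terrain segmentation

A lap elevation profile is built on a 5 m grid (`grid_m`): every fix is
assigned to its nearest grid distance on the lap axis (multi-lap tracks
fold onto one lap), altitudes are averaged per grid point, gaps are
interpolated, and the profile is smoothed with a 15 m moving average
(`smooth_m`). Two choices here deserve note:

* **Mean, not median, across laps.** Receiver altitude error drifts slowly
  (minutes), so each lap contributes an offset that is almost constant over
  a segment. A linear aggregate cancels these offsets in elevation
  *differences*; a pooled median can switch between per-lap clusters along
  the course and decouple the two ends of a segment, which we measured as
  ~1 m errors on segment elevation changes — four times the linear-noise
  level.
* **15 m smoothing window.** A moving average of width `w` rounds a grade
  kink by `w · Δg / 8`; at the sharpest corners of a typical course
  (Δg ≈ 13 pp) a 30 m window suppresses segment elevation changes by
  0.5–1 m, enough to flip segments that clear the 4 m rule by less than a
  metre. 15 m (three grid cells) keeps that bias under ~0.25 m while still
  damping point noise.

Breakpoints are placed where the sign of a *detection gradient* changes and
the new sign persists for at least `hysteresis_m = 20 m` — our reading of
"an evident change in the gradient". The detection gradient is a
wide-baseline slope (±10 m) lightly smoothed over the hysteresis scale:
near-level legs carry true grades under 1%, smaller than the noise of a
per-step gradient, and an unsmoothed sign rule fragments them. Each
breakpoint is then refined to the local elevation extremum within twice the
hysteresis window, because a crest or trough, not the smeared sign
crossing, is the physically meaningful segment end; this also undoes the
residual corner rounding of the profile smoothing.

Candidate segments are labelled by the elevation-difference rule: uphill if
the start-to-end change is ≥ `min_elev_diff_m = +4 m`, downhill if
≤ −4 m, otherwise flat. Maximal runs of sub-threshold segments are merged
into single flat segments; merged and collapsed segments are re-checked
against the threshold, and the pass iterates to a fixed point. One edge
case is deliberate: a sub-threshold run whose *net* elevation change
reaches 4 m is re-labelled uphill/downhill, keeping the invariant that a
flat segment changes elevation by less than the threshold.

Composition percentages are length shares on horizontal lengths (the
printed lengths of a course map sum to the course length); slope length is
exposed separately as `actual_length = sqrt(L_h² + Δz²)`. Turns are course
metadata supplied in configuration, never detected. An optional `gap`
interval (mismatched start/finish placement) is excluded from every
aggregate.

## Lap performance and comparison

Laps are split where cumulative distance crosses multiples of the lap
length (crossing times linearly interpolated). Speed and elapsed time are
interpolated by distance onto the common 5 m grid per lap and then averaged
across laps — averaging precedes comparison. A measured lap that stops
short of the nominal length (receiver path length rarely matches the
nominal course exactly) is extended by constant-speed extrapolation up to
2% of the lap length; larger shortfalls are an error.

Group references are pointwise means with sample (n−1) SDs, the reporting
convention in sports science; a single-member group reports SD 0.
Comparison curves and tables use the conventions: relative speed difference
is expressed as a percentage of the reference speed; positive time
differences mean the skier is slower; per-terrain time loss is the elapsed
extra time accrued in that terrain's grid cells, so terrain losses sum
exactly to the overall loss per lap. The proportion of skiing time per
terrain divides dwell time per terrain by total lap time. Per-terrain
relative-difference SDs are across grid points within the terrain; with
per-lap matrices retained in the lap series, across-lap dispersion is also
available.

## Sub-technique classification

The classifier input is the low-pass-filtered z (frontal) components of
accelerometer and gyroscope. The filter is a Butterworth low-pass (design
order 4, cut-off `cutoff_hz = 5 Hz`) applied forward and backward for zero
phase, with odd-reflection padding and endpoint-anchored state so the
passband identity is exact and edges are transient-free. Five hertz keeps
everything cyclic about classical skiing (cycle rates < 2 Hz, pole impacts
< 5 Hz) and discards vibration.

Windows are 2 s (200 samples) advancing 10 samples (95% overlap), giving
`floor((N − 200)/10) + 1` windows. Each window yields 13 features — per
channel: mean, SD, RMS, dominant frequency and its spectral power share,
zero-crossing rate; plus the circular cross-correlation peak lag between
the channels. Summary features are used instead of raw-sample distances
because the latter are sensitive to window phase. Features are z-scored by
training statistics; classification is a majority vote among the `k = 5`
Euclidean nearest neighbours (odd k limits ties across four classes), vote
ties broken by the smaller mean neighbour distance, then by the fixed class
order DP < DK < DIA < OTHER. Per-distance labels are the majority over the
windows whose centres fall in each 5 m cell; empty cells inherit the
nearest labelled cell.

The packaged training set is generated by the simulator with seed 42, 60
windows per class: 70% pure-technique windows spanning a ±15% cadence
spread, and 30% windows that straddle a technique transition, labelled by
the technique at the window centre. The transition exemplars matter: a 2 s
window inevitably mixes two signatures around every change, and with
pure-only training those mixtures fall nearest whichever class happens to
lie between the two in feature space (we observed double-pole/tuck
mixtures systematically labelled kick double poling). Users with labelled
field data can supply their own `training_set()`.

`apply_corrections()` implements the manual-correction pass used in field
practice (where visual review typically corrects on the order of 10% of
cycles): ranges of window labels are overwritten in order, overlaps warn
and later ranges win, and the corrected fraction is reported. The automatic
accuracy figures in the tests use no corrections.

## Speed-binned distribution

Each 5 m cell contributes its length (distance weighting) and dwell time
(time weighting) to the speed bin containing its midpoint speed. Bins are
0.25 m/s wide from 2 to 11 m/s, which makes the customary range endpoints
2.75, 4.75, 7 and 10 m/s all bin edges. Bins holding less than 5 m are
flagged unused rather than reported as percentages — the blank sections of
a distribution chart. Range summaries aggregate the bins inside the low
(2.75–4.75 m/s) and high (7–10 m/s) ranges weighted by bin occupancy
(equivalently: recomputed from the raw cells). Group distributions average
member percentages unweighted, excluding members for whom a bin is unused.

## The synthetic-data generator

The simulator exists so every stage can be validated against known ground
truth; no race dataset ships with the package. It emulates:

* **Course**: legs with constant grades; the packaged ten-leg 2465 m lap is
  built from printed leg lengths and incline-range midpoints and contains
  3 uphill / 3 flat / 4 downhill segments covering 37/15/48% of the course.
  Because leg-wise incline estimates do not integrate to zero net climb
  (+10.1 m per lap here) while a real closed lap must, elevation is
  uniformly de-trended by default (`close_loop = TRUE`, −0.41 pp on every
  grade); labels, lengths and composition are unchanged, and
  `close_loop = FALSE` preserves the literal per-leg arithmetic.
* **Skier**: deterministic speed `v(s) = clamp(flat_speed − sensitivity ·
  grade(s), 0.5, cap)` on a 40 m circularly smoothed grade (skiers carry
  momentum through gradient changes), defaults `flat_speed = 7.2 m/s`,
  `sensitivity = 0.45 (m/s)/%`, `cap = 10 m/s`, spanning roughly 3.3–10 m/s
  over the reference course — the realistic elite range. AR(1) noise
  (coefficient 0.9 per metre, innovation SD 0.1 m/s) models autocorrelated
  pacing variability. Ground-truth technique labels apply speed/grade
  thresholds (tuck on sustained downhills at speed; diagonal stride on
  steep slow climbs; kick double poling in the uphill transition band;
  double poling elsewhere) to the *deterministic* speed — thresholding the
  noisy speed would flicker labels on sub-second scales no skier shows.
* **GNSS**: the lap is laid out as a smooth closed loop of the right
  circumference (turn positions remain metadata; no computed quantity
  depends on plan-view turn geometry), altitude follows the profile, and
  receiver error is first-order Gauss–Markov per axis — stationary SD 0.5 m
  horizontal / 1.0 m vertical with 60 s / 300 s correlation times. Receiver
  error drifts rather than flickering fix to fix; white noise at 10 Hz
  would inflate summed step distance in a way no real receiver shows.
* **IMU**: per technique, cyclic acc_z/gyr_z templates — double poling as
  synchronized biphasic pulses (cadence 0.9 Hz), kick double poling the
  same plus one leg-kick pulse per cycle (0.8 Hz), diagonal stride as
  alternating antiphase strides with the gyroscope fundamental at half the
  1.5 Hz cadence, tuck/other near-silent — with 10% per-cycle amplitude
  jitter and additive Gaussian noise (SD 0.3).

What it does **not** emulate: satellite dropouts and multipath outliers,
barometric/GNSS altitude fusion, individual movement styles and
impairment-specific kinematics, fatigue drift, drafting and start
intervals, and snow/friction variation. Classifier accuracies on this
generator (~98% per-distance at default noise) therefore demonstrate the
pipeline's correctness, not field performance on athletes — where published
comparable systems report ~96% and a visual correction pass remains part of
the workflow.

All generators are pure functions of their seeds; a master seed derives
stream-specific sub-seeds.

## Test problem sizes

The automated suite validates on four-lap simulations of the 2465 m
reference course (~16,400 GNSS fixes, ~164,000 IMU samples, ~15,800
windows), 100-profile property sweeps for segmentation invariants, a
4,801-point window-count property, and 1,000 randomized KNN problems
against a brute-force oracle. Recovery achieved at default noise: terrain
composition within ±2 pp of truth, per-lap times within ±1 s, per-distance
technique accuracy ≥ 90%, low/high-range distribution within ±5 pp.

## Known limitations

* Segmentation assumes courses whose uphill/downhill legs carry grades
  clearly above receiver-induced gradient noise (≳2%); a course made of
  sustained 1% false flats would need a larger hysteresis or an externally
  surveyed profile.
* The 4 m rule reads endpoint elevation differences, so a segment
  combining a climb and an equal descent between evident gradient changes
  is flat by definition.
* The KNN classifier is only as general as its training windows; the
  packaged set is synthetic and idealized. Skating sub-techniques and
  cycle-level segmentation (individual pole/leg strokes) are out of scope.
* Lap splitting trusts cumulative distance; systematic path-length bias
  (heavy multipath) shifts lap boundaries accordingly.
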