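---
title: "Dynamic AOI analysis on a wide screen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic AOI analysis on a wide screen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynaoi)
```

## The measurement problem

Head-mounted eye trackers report gaze in eye-in-head coordinates, which
makes area-of-interest (AOI) analysis on a screen awkward: the screen moves
in the camera image whenever the head moves. Fiducial markers on and around
the display let the tracker's surface-mapping software re-express gaze in
screen-fixed *surface* coordinates, so a mobile tracker can serve as a
remote tracker on an arbitrarily wide display — here a three-panel,
5760 × 1200 px, ~100° wide canvas — while leaving head movements free.
`dynaoi` takes those per-surface gaze exports and turns them into dwell-time
and time-to-first-entry metrics for *moving* AOIs annotated on the stimulus
video.

Because wide surfaces map less accurately, the display is split into nine
640 × 1200 px vertical strips, each tracked as its own surface, and the nine
export streams are pooled back into one stream
(`surface_layout()`, `pool_surfaces()`). For each timestamp the sample is
taken from the surface that registered the gaze most deeply inside itself
(depth `min(x_norm, 1-x_norm, y_norm, 1-y_norm)`), with ties broken by the
lowest surface index — a deterministic rule that makes pooling independent
of file order. Coordinates are then centered: (0,0) at the display center,
+x rightward, +y downward. Everything downstream — preprocessing, margins,
matching, metrics — lives in centered coordinates; only video annotation
and rendering use native top-left pixels, converted at the boundary
(`video_to_centered()`).

The two 50 px bands occluded at the panel junctions by the bezel-correction
of the video driver are kept as metadata (`bezel_px`): gaze and AOIs share
the single video coordinate space, and no per-band remapping is applied,
since the junction bands carry no stimulus content.

## Display geometry and visual-angle margins

The three panels are modeled as one coplanar pixel grid viewed from
`viewing_distance_cm` (65 cm) — a flat-screen tangent model:

$$\theta(x) = \arctan\!\left(\frac{x \cdot p}{d}\right),$$

with pixel pitch $p$ = 0.02692 cm/px (a 24-inch 16:10 1920 × 1200 panel:
51.69 cm / 1920 px; the pitch is not printed on a datasheet we rely on, so
it is configurable) and $d$ the viewing distance. Including the four
inter-panel bezel edges (0.68 cm each) the modeled field of view is

```{r}
field_of_view_deg(screen_geometry())
```

about 101°, i.e. the nominal 100° wide design.

AOI margins compensate for eye-tracker inaccuracy and are specified in
degrees of visual angle (1–1.5° is the usual recommendation). On a flat
wide screen a fixed visual angle covers more pixels towards the periphery,
so `margins_for_box()` computes the pixel margin **separately per side**
at the box's own edges: the right margin is
`deg2px(px2deg(x_right) + m) − x_right`, and mirror-symmetrically for the
left. Top and bottom margins are both evaluated at the box's center
y-coordinate, in the vertical plane at the same viewing distance; whether
the original analysis used the slant distance to the AOI's horizontal
position instead is unknown, and the vertical-plane reading is the
simplest consistent one (vertical eccentricity is small on a 1200 px tall
display, so the difference is second-order). Margins are clamped at zero
and may push the expanded box beyond the display edge deliberately —
off-screen gaze is handled by gating, not by clipping boxes.

## Preprocessing the gaze signal

`preprocess_gaze()` applies a fixed five-stage pipeline. Parameters,
defaults and reasons:

| parameter | default | unit | why |
|---|---|---|---|
| `median_window` | 3 | samples | one-sample spike removal; medians smear less than moving averages |
| `confidence_threshold` | 0.8 | – | pupil-detection quality gate; blinks fall below it (strict `<`, 0.8 itself kept) |
| `max_interp_gap_ms` | 75 | ms | gaps shorter than this are bridged by linear interpolation (strict `<`, ties kept) |
| `gap_pad_ms` | 100 | ms | near a blink the pupil is partially occluded; ±100 ms around remaining gaps is discarded (closed interval) |
| `target_rate_hz` | 240 | Hz | two 120 Hz eye cameras in anti-phase fuse to a nominal 240 Hz but not a uniform one |

Stage order is median filter → confidence/on-screen gating → short-gap
interpolation → gap padding → uniform resampling. The median filter runs
first, on raw coordinates, so spikes cannot leak into interpolation
anchors; boundary samples with an incomplete window pass through
unchanged rather than being fabricated from a shrunken window. Gap
duration is measured between the flanking *valid* timestamps, so the run
itself is exclusive. Resampling uses Fritsch–Carlson monotone piecewise
cubic Hermite interpolation (`stats::splinefun(method = "monoH.FC")`):
linear stretches are reproduced exactly and monotone stretches never
overshoot. It is computed independently per contiguous valid segment and
**never bridges a gap** — interpolation across gaps is exclusively the job
of the 75 ms rule, which keeps Hermite polynomials from extrapolating
through blinks. Confidence and the on-screen flag are carried to the grid
by nearest neighbor (the exporter gives no rule; nearest neighbor is the
only choice that never invents intermediate confidence values).

Two numerical conventions matter at thresholds. Durations measured on a
240 Hz grid are ratios of small integers (e.g. a 24-sample gap is exactly
100 ms) that floating-point arithmetic can render as 99.999…; all
threshold comparisons therefore carry a sub-nanosecond epsilon so that
exact ties land on the side the rule prescribes (a tie is *not* "shorter
than" the threshold). Secondly, `classify_gaps()` sets gap coordinates to
`NA` immediately, so no later stage can accidentally consume them.

## Matching gaze to AOIs and the visit rules

Each 240 Hz sample is assigned to the stimulus frame whose half-open
interval $[k/\mathrm{fps}, (k+1)/\mathrm{fps})$ contains it, and tested
against that frame's margin-expanded box with closed boundaries on all
sides. Runs of hits form visits; a visit's entry and exit are the first
and last hit *sample timestamps*, so a single-sample touch has zero
duration and is removed by the minimum-dwell rule below. Gap samples end
visits exactly like non-hits.

Two rules clean the visit list (`merge_and_filter()`), in this order:

1. **Merge:** if the time between an exit and the next entry is shorter
   than 100 ms, the excursion is attributed to precision noise and the two
   visits are pooled — the bridged time counts toward the dwell.
2. **Filter:** a visit still shorter than 100 ms after merging is
   discarded; a dwell must contain at least one fixation (≈100 ms) to
   reflect any cognitive processing.

Merging before filtering matters: two 60 ms touches 50 ms apart survive as
one 170 ms visit, while filtering first would delete both. A 90 ms blink
inside an AOI does not split the dwell: the gap closes the visit, but the
merge rule bridges it. Time to first entry is measured from the object's
first appearance to the first *retained* entry — an early sub-100 ms touch
does not count (the alternative reading is defensible; this one keeps the
metric consistent with the dwell definition). Dwell percentage is
100 × total dwell / appearance time, reported uncapped with a warning if
pad/merge arithmetic pushes it over 100.

## AOI annotation

AOIs are axis-aligned rectangles (the most accessible shape for traffic
objects), one per video frame, 0-based frame indices, visibility being the
closed frame interval. Two workflows produce them:

* `interpolate_boxes()` — draw keyframes, interpolate each edge linearly
  per frame, round to integer pixels, reproduce keyframes exactly.
* `track_object()` — semi-automatic tracking by multi-scale normalized
  cross-correlation on grayscale frames. The template carries a 25%
  context ring around the box: the object boundary's position inside the
  template is what makes scale changes visible to the correlation, so the
  box grows and shrinks with the object. The template is updated *slowly*
  (kept until the correlation drops below 0.9 or a scale step is taken):
  updating it every frame would silently absorb sub-pixel-per-frame growth
  and the box would never adapt. If the best correlation falls below 0.5 —
  the object left the scene, or fills the frame — the track is declared
  lost; a later keyframe correction re-seeds it, and the lost span is
  bridged by linear interpolation so the trajectory stays contiguous. The
  tracker is deterministic by construction, and its algorithm is a
  pluggable contract: any per-frame box producer can replace it.

## Rendering

Overlay functions draw boxes (and their margin-expanded outlines) and
per-frame gaze dots — up to ~10 per participant per frame at 240 Hz, all
drawn — in colors from a fixed 26-color discriminative alphabet, cycling
beyond 26 entities. Invalid samples are simply not drawn, so blinks and
off-screen excursions are visible as disappearing dots. A video is a list
of in-memory RGB frame arrays exchanged as PNG frame directories; frames
can be rendered at a reduced `scale` (all geometry is mapped through the
same factor), which is also what the examples and tests use — a full
5760 × 1200 float frame is ~166 MB, pointlessly heavy for verification.

## The synthetic scenario generator

`generate_scenario()` emulates one recorded trial end to end: scripted
objects on linear (optionally bowed) paths with linear size ramps; gaze
that pursues a target with a configurable lag; Gaussian angular noise
applied **in degrees** and projected through the tangent model, so pixel
noise grows towards the periphery exactly as eye-tracker error does on a
wide flat screen (an optional eccentricity gain makes accuracy degrade
further with angle, emulating the characteristic peripheral accuracy
loss); blinks as runs of confidence 0.2; off-screen excursions that push
samples past the display edge so no surface registers them; and two
120 Hz eye streams offset by half a period, with optional timestamp
jitter around the nominal grid. The generator writes the same nine-file
surface-export dialect the real exporter produces, and derives the
expected pipeline result per object analytically, by interval arithmetic
over the script (gaps shorter than 75 ms healed, the rest dilated by
±100 ms, subtracted from the visibility window, then merged and
filtered). For noiseless pursuit scripts this ground truth is exact up to
sample quantization — one 1/240 s sample per visit boundary.

What the generator does *not* emulate: photorealistic stimuli, saccadic
structure within pursuit, eye-model or slippage effects, marker-detection
dropouts correlated with screen content, and real pupil-size-dependent
confidence. Passing the recovery checks therefore demonstrates that the
*pipeline arithmetic* is right under the stated conditions, not that any
particular hardware reaches a given accuracy on real recordings.

Scripted conditions used by the package's own checks: a 10 s trial at
25 fps and 2 × 120 Hz (2400 samples), a 100–260 px tracked object, three
200 ms blinks for the dwell-recovery check (each costs exactly 400 ms
after padding: 8.8 s total dwell, 88%), noise σ = 0.5° with margins
{0, 0.5, 1, 1.5, 2}° for the margin sweep, and 1000 random hit streams of
up to 500 samples for the visit-rule equivalence check. These sizes make
every property a matter of seconds to verify while keeping each effect —
quantization, padding, merging — visible at full size.

## Known limitations

* The geometry is flat and head-position-independent; there is no
  per-eye vergence or curved-screen support, and vertical margins ignore
  horizontal eccentricity (see above).
* Visit boundaries are sample timestamps, so every reported duration is
  quantized to 1/240 s and an uninterrupted stream of *N* samples has
  duration (N−1)/240 — a perfectly tracked 10 s object reports 99.96%,
  not 100%.
* The matcher is frame-by-frame by design; fixation-based AOI analysis is
  out of scope, as are saccade detection and slippage correction.
* The reference tracker is a correlation stand-in with the documented
  contract; it fails (by design, with a "lost" status) when the object
  dominates the scene or changes appearance abruptly.
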