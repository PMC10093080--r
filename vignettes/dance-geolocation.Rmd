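---
title: "From waggle runs to foraging maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From waggle runs to foraging maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wagglemap)
```

## The decoding model

A waggle phase is one straight run of the figure-eight dance. Two numbers
are decoded per run: the angle `θ` between the run and "up" on the
vertical comb (clockwise positive), and the duration `τ`, read as a
start/end frame pair and converted to seconds by the video frame rate.
On the dark dance floor "up" stands for the sun's compass direction, so

- bearing of the advertised site: `B = (A_sun(t) + θ) mod 360`,
- distance: `d = v · τ`,

with `A_sun(t)` the solar azimuth at the phase's own timestamp and `v`
the site's distance calibration factor in meters per second of waggling.
Endpoints are projected from the hive along `B` for `d` on a sphere of
radius 6371 km; at foraging ranges (≤ 10 km) ellipsoidal corrections are
sub-meter and ignored.

Assumptions worth making explicit:

- **Linearity of the distance code.** A single factor `v` relates
  duration to distance. Published dose–distance curves are nonlinear over
  kilometers, but over the few hundred meters of a feeder experiment the
  linear fit with a locally estimated `v` is the standard field practice,
  and it is what this package implements.
- **Clockwise sign convention.** The handedness of the decoded angle
  (left vs right of vertical) is a convention of the decoding protocol,
  not of the bees; this package assumes clockwise-positive so that adding
  the solar azimuth yields compass bearings directly. If a decoder uses
  the opposite convention, negate the angles on ingest.
- **True north.** Azimuths are relative to true, not magnetic, north;
  magnetic declination never enters.
- **Per-phase solar azimuth.** The azimuth drifts roughly 2–3° per
  10 minutes at midday mid-latitudes, so it is evaluated at every phase's
  timestamp rather than once per video. Timestamps are serialized at
  whole-second resolution: a second of clock error moves the azimuth by
  well under 0.01°.

## Aggregation and circular statistics

Phases aggregate to dances by `dance_id`. Direction is the circular
(vector-sum) mean — the direction of the mean unit vector — which is the
standard first-moment statistic for angles; when the mean resultant
length is numerically zero the direction is undefined and reported as
such (`mean_defined = FALSE`) rather than as an arbitrary angle.
Duration is summarized by the median by default (the mean and sd are
also carried); the median is robust to the occasional mis-scored frame
pair, and the estimator is selectable wherever it is used (calibration,
dance geocoding).

## Calibration and the sampling diagnostics

With foragers recruited to a feeder at known distance `D`,
`calibrate()` estimates `v = D / median(τ)` and reports it both exactly
and rounded to the nearest 10 m/s, matching how such factors are quoted
in the field. Three derived diagnostics describe what the recording can
resolve:

- **ring spacing** `v / fps` — durations counted in whole frames make
  decoded distances multiples of this quantum; endpoint maps show it as
  concentric rings. At `v = 380` m/s and 60 fps: 6.33 m.
- **waggle accuracy** `v / f_waggle` — the distance increment of one
  waggle cycle, the signal's own resolution. At 13 Hz: 29.2 m.
- **Nyquist margin** `fps / (2 f_max)` — whether the frame rate can
  resolve the waggle oscillation at all (the oscillation can reach
  ~18 Hz, hence 60 fps gives margin 1.67).

Sampling is *sufficient* when the ring spacing does not exceed the
waggle accuracy: then the frame clock is not the limiting term. All
three are closed forms; `diagnose()` bundles them.

## Mapping

All planar geometry happens on a local azimuthal-equidistant tangent
plane centered at the hive (x east, y north, meters). This projection
preserves bearings and distances from the hive exactly — the two
quantities the dance encodes — and its distortion elsewhere is
negligible at foraging ranges.

The "heat map" is a Gaussian kernel density with the kernel standard
deviation expressed in ground meters. The print-style radius used for
cartographic rendering of such maps has no stated ground equivalent, so
the default bandwidth is set to 29 m — the one-waggle accuracy — which
is the physically meaningful smoothing scale: structure finer than one
waggle cycle is not signal. The grid covers the endpoints plus two
bandwidths of margin, and values are rescaled so the peak is 100, with
the conventional `{0, 20, 40, 60, 80, 98, 100}%` palette thresholds
carried as default contour levels. The kernel is evaluated exactly
(separable outer products), not binned.

The search area is summarized by the density peak (argmax cell, ties
resolved toward the endpoint centroid) and by the minimal enclosing
circle of the endpoints, computed with a randomized incremental
algorithm (points outside the current circle are promoted to its
boundary; with two boundary points fixed, candidate circumcircles are
grown separately on each side of the chord). `trim_fraction` defaults to
0, so the circle bounds *all* endpoints — a deliberately conservative
search-area estimate; trimming is available for outlier-heavy data but
is an explicit analyst choice.

`sector_width()` measures angular spread as the narrowest circular arc
containing at least a coverage fraction of the bearings, by exhaustive
search over arcs anchored at observed bearings (ties: earliest anchor).
The default coverage is 0.95: for near-normal angular scatter this spans
about ±2 standard deviations, the conventional "visual sector" of an
endpoint map. Full coverage (1.0) is available but is dominated by the
single most extreme phase.

## Solar geometry

`solar_position()` implements the NOAA general solar-position equations
(Julian century → mean longitude/anomaly → equation of center → apparent
longitude → declination and equation of time → hour angle → azimuth/
elevation). Atmospheric refraction is applied to the *elevation only*;
azimuth is purely geometric. Accuracy is well under 0.1° over 1950–2050,
verified in the test suite against an independently implemented
Michalsky-style ephemeris on random instants and places (the acceptance
contract is ≤ 0.5°, two orders of magnitude below the dance's intrinsic
angular scatter). Validity is restricted to years 1900–2100; latitudes
beyond the polar circles are accepted but azimuth becomes `NA` only in
the exactly degenerate configurations (sun at zenith, observer at a
pole).

## The synthetic session generator

`sim_config()` defines the study conditions; `simulate_session()` draws
them reproducibly from a single seed. The defaults describe a midsummer
10-minute feeder session at a mid-latitude western-European site
(46.15° N, 0.64° W, UTC+2): a feeder 230 m due east, true factor
380 m/s, 141 dances of 8–14 phases (mean ≈ 10.6), per-phase duration
noise sd 0.14 s quantized to 1/60 s frames, wrapped-normal angular noise
sd 13.5°, and a per-dance waggle frequency drawn from N(12.67, 1.89²) Hz.
The angular sd is a modeling choice set so that ±2σ ≈ a 54° sector, the
spread a feeder-validation map shows; it is a default, not an asserted
measurement. Wrapped-normal noise is used rather than von Mises — at
these concentrations the two are practically indistinguishable and the
wrapped normal is cheaper to reason about.

The generator reproduces the features of real decoded data that the
pipeline is sensitive to: solar-azimuth drift across the session (the
true dance angle changes through the 10 minutes), frame quantization of
durations (re-derived from rounded frame counts, so the distance rings
appear), truncation of durations at one frame, and per-dance phase-count
variation. It does *not* model dance attrition, follower behavior,
within-dance duration correlation (the noise is i.i.d. per phase — a
documented simplification), misdirection under visible sky, or distance-
dependent scatter. Passing recovery tests therefore demonstrate that the
*pipeline arithmetic* is correct under realistic noise, not that real
colonies meet these error bounds.

A configuration whose duration noise would truncate more than half of
all draws at the frame quantum is rejected as a configuration error —
such a model no longer resembles a dance duration distribution.

## Numerical choices

- Angles are normalized to [0, 360) everywhere; angle differences are
  reported in (−180, 180].
- Great-circle distances use the haversine form (numerically stable at
  short range, unlike the arc-cosine form, which loses ~0.1 m at
  hundreds of meters); initial bearings use the standard spherical
  `atan2` formula, the exact inverse of the destination formula.
- Distance 0 projects to the hive coordinates bit-exactly.
- The minimal-enclosing-circle containment tolerance is 1 cm; its
  internal shuffle uses a fixed linear-congruential permutation so
  results are deterministic and the caller's RNG state is untouched.
- The density grid anchors at `min(coordinate) − 2·bandwidth` in each
  axis, so a rigid translation of all endpoints translates the grid with
  them (values stable to ≪ 1%).
- Frame counts, not durations, are the stored truth; durations are
  always re-derived as `(frame_end − frame_start) / fps` and are exact
  multiples of `1/fps`.

## Problem sizes

The shipped tests and examples run at the scale of the emulated session:
~1,500 phases / 141 dances per run, density grids of a few thousand
cells (5 m cells over a few hundred meters), 20-seed replicate sweeps
for the recovery checks, and 100-sample ephemeris comparisons. These
sizes were chosen to match the field study the generator emulates; all
complete in seconds on a single core.

## Known limitations

- The calibration is a single linear factor; extrapolating it far beyond
  the calibration range (e.g., kilometers from a 230 m feeder) inherits
  the linearity assumption.
- Magnetic declination, terrain, and elevation differences between hive
  and forage site are out of scope.
- The dance-angle sign convention must match the decoder's; it is not
  auto-detected.
- `η`, the dance duration summary, is interpreted as the median; if a
  decoding protocol defines it otherwise, pass `estimator = "mean"`.
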