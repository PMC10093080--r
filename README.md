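# wagglemap

Returning honeybee foragers advertise a profitable resource by waggle
dancing on the vertical comb. The straight "waggle" run of the figure-eight
encodes a polar coordinate: its angle from vertical equals the angle
between the sun's azimuth and the direction of the resource, and its
duration is proportional to the distance. A recording hive with a fixed
camera over the dance floor therefore turns a colony into a distributed
survey instrument — provided the decoded runs can be mapped back onto the
ground.

`wagglemap` is that mapping layer, written for behavioral ecologists who
decode dance videos (by eye or by software) into tables of waggle phases.
It converts phase records — frame-timed durations and angles from vertical
— into georeferenced vector endpoints and search-area density maps, and
supplies the calibration and sampling diagnostics the decoding needs.

## The model

For a waggle phase with angle from vertical `θ` (degrees, clockwise) at
UTC instant `t`, observed at a hive at latitude/longitude `(φ, λ)`:

- **bearing**: `B = (A_sun(t, φ, λ) + θ) mod 360`, where `A_sun` is the
  solar azimuth (degrees clockwise from true north), computed with the
  NOAA general solar-position equations;
- **distance**: `d = v · τ`, where `τ = (frame_end − frame_start) / fps`
  and `v` (m/s) is the site's distance calibration factor, estimated
  against a feeder at known range as
  `v = distance_feeder / median(τ)`;
- **endpoint**: the great-circle destination at bearing `B` and distance
  `d` from the hive on a sphere of radius 6371 km.

Dance-level endpoints use the circular (vector-sum) mean of the phase
angles and the median phase duration. Because durations are measured in
whole frames, distances are quantized in steps of `v / fps` ("rings"),
and the per-waggle ground accuracy is `v / f_waggle` for a waggle
oscillation at `f_waggle` Hz. The endpoint cloud is summarized by a
Gaussian kernel density ("heat map") on a local tangent plane and by a
minimal enclosing circle.

## Worked example

Simulate a 10-minute feeder session (141 dances recruiting to a feeder
230 m east of a hive at 46.15° N, 0.64° W, midsummer midday) and run the
full pipeline on the resulting phase CSV:

```r
library(wagglemap)

cfg <- sim_config(seed = 1)           # the defaults are the feeder-study conditions
sim <- simulate_session(cfg)
dir <- tempfile(); write_session(sim, dir)

rc  <- run_config(cfg$site, feeder_distance_m = 230, session_len_min = 10)
rep <- run_pipeline(rc, file.path(dir, "phases.csv"), file.path(dir, "out"))
```

The report (also written to `out/report.json`) contains:

```
n_phases: 1531   n_dances: 141
dance rate: 14.1 dances/min  -> 14
calibration v: 383.33 m/s    -> about 380 m/s
ring spacing: 6.39 m   waggle accuracy: 29.49 m   nyquist margin: 1.67
sector width (95% of phase bearings): 52.7 degrees
search-area peak: (46.15000, -0.63702)   enclosing diameter: 111.1 m
```

Reading these numbers: the self-calibrated factor recovers the true
383 m/s within 1%; the 52.7° sector reflects the angular scatter of
individual phases; the density peak lies half a meter from the true
feeder position (46.15000, −0.63701); and the diagnostics confirm that at
60 fps the 6.4 m distance quantum is well below the 29.5 m one-waggle
accuracy, i.e. the frame clock is not the limiting resolution.
`recovery_report()` packages this comparison against a known feeder:

```r
recovery_report(sim$phases, cfg$site,
                list(bearing_deg = 90, distance_m = 230),
                calibration_mode = "self", v_true = 380)
#> $v_estimated                  383.33
#> $median_abs_bearing_error_deg 3.04
#> $peak_to_feeder_m             0.51
#> $enclosing_diameter_m         111.1
```

Output formats: phase/dance CSVs, endpoint GeoJSON (WGS84 Point
features) and CSV, and the density grid as an ESRI ASCII `.asc` file.
The `.asc` coordinates are in a local azimuthal-equidistant tangent plane
centered on the hive (x east, y north, meters); the sidecar
`density.asc.crs.json` records the hive latitude/longitude anchoring that
plane.

A thin command-line wrapper with `simulate`, `diagnose` and `run`
subcommands is installed at `inst/cli/wagglemap.R` (exit codes: 0
success, 2 validation error, 3 configuration error).

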