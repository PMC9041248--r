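# moonwatch

An R toolkit for **moon-watching**: quantifying nocturnal bird migration by
counting the silhouettes of migrants crossing the moon's disk through a
telescope. It is written for ornithologists and aeroecologists who want to
run, or build software for, automated moon-watching stations — and for
anyone who needs a fully ground-truthed testbed for silhouette detection on
lunar video.

The package implements the complete measurement chain in software:

* **`scene_sim`** — a synthetic lunar-video simulator: a bright anti-aliased
  moon disk drifting across a dark frame, dark elliptical silhouettes
  crossing it on physically sampled paths, optional maria, fog, and frame
  timing jitter, with an exact machine-readable ground-truth log for every
  frame.
* **tracking** — the closed-loop visual servo that keeps the drifting moon
  in frame: threshold segmentation, binary centroid, deadband-gated
  proportional pulses to a simulated two-axis alt-azimuth mount, with a
  per-session calibration probe and a cloud-tolerant loss policy.
* **timing** — a checkpointed wall-clock/frame-count log and piecewise-linear
  per-frame time reconstruction, because software-timed cameras cannot be
  trusted to hold their nominal frame rate.
* **transit detection** — automated silhouette annotation: per-frame disk
  fitting, a background model that suppresses static lunar features,
  connected-component detection down to 2 px blobs, nearest-neighbour track
  linking, and flock grouping.
* **analytics** — compass flight bearings from image tracks via the
  projection model below, body orientation and wind-drift angles,
  distance-from-apparent-size estimates, a circular direction rose, and the
  Lowery-style **migration traffic rate**.

## The core model

For a bird in level flight with ground-track bearing *β*, seen against the
moon at azimuth *A* and altitude *θ*, the image-plane velocity is

```
u = sin(β − A)          (horizontal)
w = −cos(β − A)·sin θ   (vertical, up)
```

so a measured image path angle inverts to *β* = *A* + atan2(u, −w/sin θ),
with no 180° ambiguity because the direction of motion is known. The
viewing cone through the disk, cut at an assumed flight altitude *H*, is an
ellipse with semi-axes *a* = (δ/2)·H/sin θ and *b* = *a*/sin θ (δ = lunar
angular diameter); a bird with bearing β crosses a gate of width

```
gate(β) = 2·sqrt(a²·sin²ψ + b²·cos²ψ),   ψ = β − A
```

and the traffic rate is Σ 1/gate(β) over birds, per hour of watch —
birds per km of front per hour (per-mile values use statute miles).

## Worked example

Simulate one minute of a migration night of known flux, then run the full
detect → link → analyze chain:

```r
library(moonwatch)

geom  <- session_geometry(moon_azimuth_deg = 160, moon_altitude_deg = 55)
scene <- scene_config(rng_seed = 42, geometry = geom)

schedule <- sample_transit_schedule(
  density_per_km_h = 4e5, flight_altitude_m = 500,
  direction_distribution = direction_vonmises(340, 4),
  duration_s = 60, scene = scene, seed = 42)
length(schedule)
#> [1] 51

result <- full_pipeline(scene, schedule, duration_s = 60)
result$performance[c("recall", "precision")]
#> $recall
#> [1] 1
#> $precision
#> [1] 1

result$summary$circular_mean_bearing_deg
#> [1] 337.2377
result$summary$circular_mean_north_of_east_deg
#> [1] 112.7623
result$summary$traffic_rate
#> Traffic rate: 470138.6 birds/km front/h (756614.8 birds/mile front/h)
#>   from 51 tracks (50 with bearings) over 0.02 h, H = 500 m
```

All 51 scheduled transits are recovered with no false tracks. The circular
mean bearing (337° compass, also reported in the classical "north of east"
convention as 113°) recovers the von Mises mean of 340°. The traffic-rate
estimate of 4.7×10⁵ birds/km·h brackets the true simulated flux of
4×10⁵ — a one-minute watch of ~50 birds carries about ±15% of Poisson
sampling noise, and the estimator is unbiased over longer sessions (the
test suite pins it within 10% at ≥200 transits across moon altitudes
20–90°).

A closed-loop tracking session, and the command-line interface over the same
functions:

```r
sc <- scene_config(fps_nominal = 1, drift_rate_deg_per_min = 0.25)
tc <- tracker_config(work_width_px = sc$frame_width_px,
                     work_height_px = sc$frame_height_px,
                     min_moon_area_px = 0.25 * pi * moon_radius_px(sc)^2)
s  <- simulate_session(sc, list(), duration_s = 7200,
                       tracker = tc, plant = mount_plant())
# the moon never leaves the frame; corrections ~every 25 s
```

```sh
Rscript inst/cli/moonwatch run-all --out out/ --duration 30 --density 2e5 --seed 1
```

Sessions written to disk consist of a numbered PNG frame sequence, a
plain-text timestamp log, ground truth as JSON lines, per-track CSV/JSONL,
and a JSON summary with the rose, both direction conventions, and the
traffic rate in both units.

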