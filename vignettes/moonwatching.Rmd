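---
title: "Quantifying nocturnal bird migration by automated moon-watching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nocturnal bird migration by automated moon-watching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moonwatch)
```

## The method

Moon-watching counts nocturnal migrants by pointing a telescope at the full
moon and logging the dark silhouettes that cross its disk.  The classical
protocol (Lowery's, from the 1950s) was manual: an observer watched through
an eyepiece, called out transits, and later converted counts and directions
into a *traffic rate* — birds crossing a unit line of front per hour.
A modern automated station replaces the observer with a camera on a motorized
alt-azimuth mount, a closed-loop tracker that keeps the drifting moon in
frame, and video analysis that finds, times, and measures every transit.

`moonwatch` implements that whole measurement chain in software, paired with
a synthetic lunar-video simulator that knows the exact truth behind every
frame.  Every stage of the analysis can therefore be validated end to end
without field recordings: the simulator *is* the instrument standard.

## The simulator and what it emulates

`scene_config()` describes a frame: an anti-aliased bright disk (default
230/255) of the moon's angular diameter (0.52°) against dark sky (10/255),
drifting linearly across the image at a configurable rate.  Defaults follow
a typical digiscoped field setup: a field of view of about 1° so the moon
fills 50–70% of the frame height (the working value is configurable because
real eyepiece/camera combinations vary), ~0.25°/min of apparent lunar drift,
and a nominal 15–30 frames/s camera whose true frame times can jitter by a
configurable fraction of the frame period, emulating software-timed capture.
Optional static dark blotches stand in for lunar maria, and a multiplicative
fog factor (possibly time-varying) emulates cloud and mist.

Birds are `transit_spec()`s: a compass ground-track bearing, a tail-to-beak
body orientation, an image-plane angular speed, a silhouette length (drawn
as a filled 3:1 ellipse — real silhouettes are irregular, but any compact
dark blob exercises the detector identically), a darkness level, and a
signed chord offset fixing where the path crosses the disk.  The transit
geometry is frozen relative to the disk for the second or two a crossing
lasts; lunar drift is orders of magnitude slower than bird image motion, and
freezing it keeps entry/exit truth exact.  An `erratic` option produces a
slowly wandering blob as a non-bird distractor.

`sample_transit_schedule()` places birds physically: a uniform horizontal
flux (birds per km of front per hour) at an assumed flight altitude, with
bearings from a uniform or von Mises direction field, thinned by the width
of the viewing gate each bearing sees.  Because the sampler works in flux
units, the realized transit counts carry the true flux, which is what lets
the traffic-rate estimator be tested for bias.  A session's expected count
is validated in the test suite against an independent Monte-Carlo rain of
straight 3-D tracks intersected numerically with the viewing cone.

What the simulator does *not* model: lunar surface texture beyond crude
maria, atmospheric seeing, wing-beat modulation of silhouette shape, and
finite-distance perspective within a transit.  Passing tests therefore
demonstrate the correctness of the algorithms under idealised imaging, not
detector performance on difficult real footage.

## Tracking the moon

The tracker reproduces a field station's control loop: every few seconds it
extracts a working-resolution frame (`extract_tracking_frame()`, default
800×600, by monotone nearest-neighbour resampling), segments the moon with a
user-adjustable threshold, takes the *binary-mask* centroid (robust to
exposure changes above threshold), and compares it with a reference point
near the frame centre.  Inside a deadband (default 12.5% of the working
height) nothing happens — the mount stays motionless so the video stays
still.  Outside it, proportional-duration pulses are sent to the two mount
axes until the error falls below half the deadband; the half-deadband
hysteresis prevents chatter at the boundary.

Two details are deliberately pragmatic.  First, the pulse scale and axis
signs are measured, not assumed: at session start the loop fires a short
probe pulse on each axis and observes how the centroid moves, since optical
inversions differ between scopes.  Second, loss handling is a patience
counter: clouds make the fix invalid, and only five consecutive invalid
evaluations (default) count as complete loss, which terminates the session
cleanly — shorter occlusions simply resume.  With the default geometry and
0.25°/min drift the loop corrects about every 25 s; the correction interval
scales as (deadband angle)/(drift rate), so wider fields or slower drift
stretch it toward minutes.

## Timing

Software-timed cameras do not deliver frames at their nominal rate, so all
transit timing runs through a checkpoint log: wall-clock time and cumulative
frame count, once per second by default.  `frame_time()` reconstructs any
frame's capture time by piecewise-linear interpolation in frame count —
exact at checkpoints, never extrapolating.  With ±20% frame-period jitter
the reconstruction error is bounded by one true frame period, which is also
the duration assigned to single-frame transits (0.04 s at an effective
25 fps).  The log is line-oriented text with a `#` header carrying camera
settings; frames round-trip as numbered PNG sequences.

## Detection and tracking of silhouettes

Silhouettes are only visible against the lit disk, so detection is
restricted to the disk interior (minus a ~1.5 px anti-aliased rim band where
no brightness model is reliable).  A pixel is a candidate when it is darker
than the local disk brightness — the median of the inner disk, so fog-dimmed
sessions adapt automatically — by at least `contrast_threshold` (default 40
levels), *and* darker than a running background frame re-registered to the
disk centre.  The background is an exponential moving average with a ~1 s
half-life: static dark features (maria, craters) are absorbed into it and
vetoed at the component level, while anything that moves is not.  Connected
components of at least 2 px (the smallest real silhouettes are only a few
pixels) become detections with darkness-weighted centroids and second-moment
axis estimates.

Tracks are built frame-wise by greedy nearest-neighbour association with a
constant-velocity prediction.  The association gate is the larger of 0.35
disk radii and the displacement of the fastest plausible bird (2.5°/s by
default) over the local frame period, scaled per elapsed frame — a fixed
pixel gate would fragment fast transits at low frame rates.  A track
survives one missed frame, and is retired immediately once
its predicted position leaves the disk — an off-disk bird is invisible, and
this rule prevents one bird's exit being bridged onto another bird's entry.
Track duration is last time minus first time plus one local frame period.
Tracks are labelled `full_crossing`, `edge_skirting` (all detections within
a body length of the rim), or `single_frame`; nothing is discarded, because
edge and single-frame birds are real data.  Tracks with straight-line R²
below 0.8 or angular speed below 0.05°/s are *flagged* as possible insects,
never deleted — no validated criterion separates birds from insects, so the
flag is advisory.  Coincident tracks are grouped into flock events by
single-linkage on temporal overlap within a 2 s window.

On simulated sessions of 52 transits per 40 s (up to ~5 simultaneous birds,
3–15 px silhouettes, ≥60 levels of contrast) the chain recovers over 99% of
transits with ~98% precision, including edge-skirters and single-frame
blips; the acceptance suite pins both at ≥0.95 over 520 transits.

## From image tracks to compass directions

For a bird in level flight with ground-track bearing β, seen against the
moon at azimuth A and altitude θ, the image-plane velocity components are

u = sin(β − A),  w = −cos(β − A)·sin θ,

with u along the local horizontal and w up; the image path angle is
atan2(w, u) after camera roll and mirror flips.  The inversion
β = A + atan2(u, −w/sin θ) uses the direction of motion, so there is no
180° line ambiguity.  Near the horizon (θ ≤ 5°) all bearings foreshorten
onto horizontal image motion and inversion is refused; above θ = 85° it is
returned with a wide-uncertainty flag because the azimuth reference itself
degenerates at the zenith.  The test suite validates the round trip against
an independent perspective-projection oracle to better than 1°.

Body orientation uses the same projection on the silhouette's major axis:
per-frame axis angles (axial quantities, averaged after angle-doubling) need
a minimum 1.5:1 elongation on at least 3 frames, the head end is picked by
the direction of motion, and the drift angle is the wrapped difference
between track bearing and body bearing — zero for a perfectly
wind-compensating flyer.  Simulated flyers with 0° and 20° offsets are
recovered within 3°.

The moon's azimuth, altitude and apparent diameter come either from the
scene configuration (simulations) or from `moon_topocentric()`, a truncated
analytic lunar theory (the dominant periodic terms of lunar longitude,
latitude and distance, with eccentricity damping, plus standard sidereal
time, obliquity, and a small-angle parallax correction in altitude).  Its
geocentric accuracy is a few arcminutes — far tighter than the ~0.2°
needed to rotate direction references — and it is cross-checked in the test
suite against a second, independent low-precision series and a published
benchmark epoch.  Refraction and nutation are neglected at this accuracy.

## Distance from apparent size

The moon anchors the plate scale: its angular diameter over its fitted pixel
diameter gives radians per pixel.  With the classical passerine assumption
(all migrants 10–100 g, body length 0.08–0.25 m, default 0.15 m), distance
follows from length/angular-size.  Sub-resolution silhouettes (<2 px) yield
lower bounds only.  These are order-of-magnitude figures: the assumed body
length dominates the error, exactly proportionally.

## The traffic rate and its gate geometry

The viewing cone through the disk, cut horizontally at the assumed flight
altitude H, is an ellipse: slant range D = H/sin θ, horizontal semi-axis
a = (δ/2)·D and along-azimuth semi-axis b = a/sin θ, where δ is the moon's
angular diameter in radians.  A bird with bearing β crosses a gate of width

gate(β) = 2·sqrt(a²·sin²ψ + b²·cos²ψ),  ψ = β − A,

and contributes 1/gate(β) birds per unit front; the sum over birds divided
by the watch duration is the traffic rate.  Birds without a solvable bearing
(single-frame tracks) are counted at the mean reciprocal gate of the birds
with bearings.  At the zenith the gate is circular, δ·H ≈ 9.08 m for
H = 1000 m, and 45 birds/h give 4958.3 birds/km·h — the closed form the
acceptance suite checks to four significant figures.  Applied to simulated
sessions of known flux the estimator is unbiased within Monte-Carlo error
across moon altitudes 20–90° and both uniform and von Mises direction
fields (the suite requires 10% at ≥200 transits).  The flat-earth
horizontal-flight gate is adequate below a few kilometres of altitude; the
flight altitude itself is an assumption parameter (default 500 m), since
moon-watching cannot measure it per bird — though distance-from-size
estimates can inform it.

Directions are stored as compass bearings (clockwise from north); the
historical reporting convention "degrees north of east" (counterclockwise
from east) is emitted alongside, converted as 90° − bearing (mod 360).  Both
are reported because the historical phrasing is ambiguous enough that
readers should see the two conventions side by side.  Per-mile rates use
statute miles (×1.609344) — note that some historical reports appear to mix
nautical-like factors, which is why the package emits both units explicitly
rather than one derived figure.

## Numerical choices and degenerate inputs

Frames are 8-bit grayscale matrices; coverage-based anti-aliasing is used
for both disk and silhouettes, so the segmentation pixel-count oracles in
the tests are exact to ±1 px.  The equivalent-disk radius `sqrt(area/π)`
under-reads a gibbous moon by about `sqrt(illuminated fraction)`; the fit
records the bias (centre shifted toward the lit limb) rather than modelling
phase.  An all-dark frame is a skip signal for analysis and an invalid fix
for the tracker; a moon off-frame renders as pure sky and exercises the
loss policy.  Zero-density schedules, zero-track sessions, and empty roses
are all defined, flagged outputs rather than errors.

## Problem sizes used in the shipped checks

The acceptance suite and `scripts/acceptance.R` use a 256×192 px scene at a
1° field of view (moon radius ≈ 67 px): a two-simulated-hour tracking
session at 1 frame/s, ten detection sessions of 52 transits each (520 total),
1500-frame timing reconstructions, 50-configuration projection round trips,
and four-altitude flux-recovery runs of ≥200 transits each.  These sizes
were chosen so the full validation runs in a couple of minutes on a single
core while every Monte-Carlo comparison retains enough statistics for its
stated tolerance.

## Known limitations

* The simulator's silhouettes are rigid ellipses on an untextured disk;
  real-footage detection will need threshold retuning and likely a richer
  background model.
* Bird/insect separation is advisory flagging only.
* The ephemeris neglects refraction (up to ~0.1° below 10° altitude), which
  only matters for sessions analysed unusually close to the horizon — where
  the direction inversion is refused anyway.
* No search-pattern recovery after complete loss of the moon: the session
  ends with an error, mirroring how a field station would behave.
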