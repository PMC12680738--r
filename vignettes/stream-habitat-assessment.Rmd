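---
title: "Drone-based stream habitat assessment with streamhab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drone-based stream habitat assessment with streamhab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamhab)
```

## What the package does

`streamhab` covers the computational side of a drone-based stream habitat
survey for small (wadeable) streams in planar metric coordinates:

1. **Flight planning** — an obstacle-aware boustrophedon ("S-shaped")
   coverage route at a high survey altitude for the whole site and a low
   altitude for the stream corridor, with image-overlap-driven line
   spacing, grid-based detouring around buffered obstacles, route
   simplification and a battery feasibility check.
2. **Habitat parameter extraction** — spatially continuous station series
   of wetted width, bank-top width, per-side erosion / riparian-buffer /
   in-stream-cover widths, depth, wetted fraction, a velocity proxy, plus
   pool intervals, bends, sinuosity and channel gradient, all measured
   from delineated bank and habitat-layer polygons.
3. **Multi-metric index (MMI) scoring** — nine physical metrics
   categorised as excellent / good / fair / poor (scores 10 / 7.5 / 5 /
   2.5), summed into a site score and an overall class, in three modes:
   spatially continuous, transect-sampled, and vicinity-based
   (worst-in-window).

Everything operates on vector inputs (GeoJSON) that a practitioner would
digitise from orthophotos; photogrammetric reconstruction itself is out of
scope.  A parametric meander generator with analytically known ground
truth makes the whole pipeline testable without any external data.

## Flight-route model

**Line spacing.** For a camera with cross-track field of view $\phi$ at
altitude $h$, the ground footprint across the flight direction is
$2h\tan(\phi/2)$.  Adjacent parallel lines spaced
$\Delta d = 2h\tan(\phi/2)\,(1-\omega)$ overlap by the fraction
$\omega$.  Defaults target $\omega = 0.75$ overall and $\omega = 0.90$
over a 10 m corridor around the stream; the camera model is configurable
because the spacing, not the hardware, is the contract.

**Sweep.** Horizontal sweep lines are laid bottom-to-top at spacing at
most $\Delta d$, tightened to the focus spacing wherever the band up to
the next coarse line would overlap the focus corridor, clipped to the
boundary and joined end-to-end in alternating direction.  Sweep lines are
`survey` edges, connectors are `transit` edges; the two classes carry
different speeds (1 / 2 m s⁻¹ at low elevation, 4 / 8 m s⁻¹ at high
elevation by default).

**Obstacles and detouring.** Obstacles are dilated by a 5 m clearance
buffer (round joins) and rasterised conservatively onto an occupancy grid
(any touched cell is blocked; default cell 1 m).  A route edge that
crosses a blocked cell is replaced by the optimal grid path between its
endpoint cells: Dijkstra over (cell, heading) states on the 8-connected
lattice with $\sqrt2$ diagonals, minimising path length first and the
number of turns second, with a fixed neighbour expansion order making the
result fully deterministic.  Diagonal moves past a blocked orthogonal
neighbour are forbidden ("no corner cutting"); combined with conservative
rasterisation this guarantees that every point of a detoured route keeps
at least the buffer distance to the raw obstacle polygons.  Incremental
replanning machinery is deliberately omitted: survey maps are static, so
a single-shot optimal search is the testable contract.

**Simplification** applies two rules per same-class run of edges:
strictly collinear interior nodes are removed, then a greedy
line-of-sight pass drops any interior node whose bridging segment crosses
no blocked cell.  Path length never increases and obstacle avoidance is
preserved (both are re-checked property-style in the test suite against
an independent igraph Dijkstra oracle on randomized grids).

**Flight time** is the class-weighted sum of edge lengths plus a 30 s
liftoff/landing overhead; a route is feasible when it fits within 75 % of
a 20-minute battery.

## Centerline model

The stream centerline is the medial axis of the channel bounded by the
two bank polylines — the locus of points equidistant from both banks.
With exactly two bounding curves the medial axis needs no Voronoi
machinery or skeleton pruning: nodes seeded at matched-arc-length
midpoints of the banks are iterated to the fixed point of
$p \mapsto \tfrac12\bigl(\mathrm{nearest}_L(p) + \mathrm{nearest}_R(p)\bigr)$,
which converges to the equidistant locus, then resampled at uniform arc
length.  The channel end edges are not banks, so the equidistant locus is
degenerate there; the end nodes therefore stay anchored at the midpoints
of the bank endpoints.  On a rectangular channel this reproduces the axis
of symmetry to machine precision; on offset-generated meanders it stays
within a couple of centimetres of the generating curve at the default
0.5 m bank densification.

Derived quantities:

* **Sinuosity** — centerline length over the straight distance between
  its endpoints.
* **Bends** — nodes where the heading change across a moving arc-length
  window exceeds a threshold (default 30°); contiguous super-threshold
  runs collapse to the angle-maximal node.  The window (default 5 m) is a
  noise-immunity device: a raw per-vertex turning angle on a finely
  sampled centerline is dominated by discretisation jitter.  Coarse
  polylines are internally resampled at a quarter window.
* **Gradient** — elevation drop per unit channel length.  Both the
  end-to-end slope and the length-weighted mean of per-segment slopes are
  available (`channel_gradient()`, `gradient_profile()`); they coincide
  by telescoping when weighted by segment length, and the distinction
  matters only for irregularly sampled profiles.

## Parameter measurements

**Wetted width** at a station is the shortest bank-to-bank chord through
the centerline node, scanned at 1° angular resolution (coarse-to-fine),
minus any part of the chord crossing an island.

**Lateral widths** (erosion E, riparian buffer B, in-stream cover F) are
measured along the chord's supporting ray on each side.  The in-channel
part of the ray counts in full, so disjoint in-stream cover patches
accumulate.  Beyond the bank, covered intervals accumulate only while
they chain from the bank with gaps of at most `gap_m` (default 1 m).
The chaining rule is deliberate: a long unanchored ray on a meandering
channel eventually pierces the riparian zones of *other* meander limbs,
which belong to those limbs' banks, not to the station being measured.
One metre of tolerated gap lets a buffer zone sit behind a narrow eroded
strip while still excluding detached polygons.

**Bank-top width** is the distance between the crossings of the chord's
line with the two bank-top polylines; a side with no crossing within
reach yields a flagged missing value rather than zero.

**Depth** is water-surface elevation minus bed elevation, with the bed
linearly interpolated in arc length between the projections of the bed
sample points onto the centerline.  This assumes a gradually varying bed;
abrupt steps between samples are smoothed over, so absolute depths are
the least certain parameter.  Negative depths are clipped to zero and
counted.

**Velocity proxy.** No velocimetry is available from still imagery, so
stations are ranked by continuity: at roughly constant discharge,
section-averaged velocity scales as $1/(W\,D)$.  Only the ordering enters
the pool rule, so the unknown discharge cancels.

**Pools** are maximal runs of stations that are simultaneously deep
(depth above the 70th percentile of stations, strict), slow (velocity
proxy below the 30th percentile, strict) and smooth-surfaced (white-water
pixel fraction below 0.10).  The slow criterion is stated in the
protocols as "velocity below 70 % of transects", which is ambiguous
between "below the value that 70 % exceed" and "slower than 70 % of
stations"; the package reads it as the mirror image of the depth
criterion (slower than 70 % of stations, i.e. below the 30th percentile)
and exposes the percentile as `vel_pct` so the other reading is one
configuration away.  When white-water fractions are absent the third
criterion is skipped with a warning.  Percentiles use the standard
linear-interpolation definition (R type 7).

**Wetted fraction** is measured chord-wise (dry length over in-channel
chord length); an area-based variant would differ only at strongly
asymmetric dry zones.

## Scoring model

Metric values map to categories through a fixed threshold table with
four bins per metric.  Two metrics carry separate threshold systems for
high-gradient and mild-gradient channels, selected by whether the channel
slope exceeds 0.02 m/m (strict).  Three details worth noting:

* The pool-percentage metric (M9) is non-monotone: mid-range pool shares
  score excellent, and both pool-free and pool-saturated reaches score
  poor.  Its interval closures are implemented exactly as published.
* The high-gradient variant of the sinuosity metric duplicates the
  width/depth-ratio thresholds in the published table (it is stated as a
  riffle-spacing-to-width ratio).  It is implemented as printed and
  flagged here: for high-gradient channels the caller must supply that
  ratio, not the sinuosity.
* Buffer and erosion (M2, M3) are measured per bank side.  Two-sided
  metrics contribute the *mean of their side scores* to the total — the
  unique simple rule consistent with both published demonstration totals
  (43.75 and 47.5).

Spatially continuous metrics additionally report a length-weighted
category distribution over the stations.  The site-level category of such
a metric is derived, by default, by binning the length-weighted mean
parameter value; `site_rule` switches to majority-category or
worst-category, since the mapping from a distribution to one category is
a genuine design choice with no single published answer.  Ratio metrics
(width/depth) use the ratio of means, not the mean of ratios.

The total over M2–M9 classifies the site at `>= 60` excellent,
`[45, 60)` good, `[30, 45)` fair, `< 30` poor.

**Assessment modes.** `assess_continuous()` scores the full station
series.  `assess_transects()` samples `n` equally spaced stations
(default 14) and scores transect means — mirroring a tape survey, and
inheriting its blindness to impairments between transects.
`assess_vicinity()` reports, per transect, the worst station category
within half a transect spacing on either side; it never reports better
than the transect mode at the same transect and is the mode of choice for
locating impairment hot-spots.

## The synthetic generator

`meander_spec()` / `generate_site()` build a sine-generated channel
$y = a\sin(2\pi x/\lambda)$ with banks offset by half the width profile
along the analytic normals, bank tops and habitat layers as further
offset strips, islands as in-channel strips, bed points from the depth
profile, and per-station white-water fractions.  Sine meanders were
chosen over arc-based planforms because tangents are analytic and arc
length reduces to a quadrature, so sinuosity, bend stations and all width
profiles are known exactly; generation refuses specs whose half-width
reaches the minimum curvature radius.  Everything is seed-deterministic,
including the rejection-sampled obstacle fields.  `degrade()` inserts a
localized impairment (buffer loss, erosion widening, cover or debris
removal) and regenerates ground truth alongside, which drives the
transect-blindness experiments.

What the generator does **not** emulate: imagery and photogrammetric
error (inputs are exact polygons, so passing tests bound algorithmic
error only, not delineation error), hydrodynamics (the white-water
fraction is specified, not simulated; depth steps at pool edges are
ramps of one bed-sample spacing, default 1 m), braided or multi-thread
channels, and vertical bank structure.

## Numerical choices and problem sizes

* Default station spacing 1 m for extraction tests, 0.5 m geometry step
  in the generator; fixtures span 100–250 m of channel — small enough for
  the full suite to run in about a minute, large enough that percentile
  rules and length weighting are exercised on hundreds of stations.
* Chord minimality is resolved to 1°; lateral rays reach 100 m with a 1 m
  chaining gap.
* The route searches are property-tested on 100 randomized occupancy
  grids up to 50×50 against an independent igraph Dijkstra oracle; path
  costs agree to 10⁻⁹.
* Interval closures at bin boundaries are exact (no tolerance); only the
  100 % wetted bin accepts a 10⁻⁹ slack for floating-point station means.
* Degenerate inputs fail loudly: crossing banks, geographic CRS,
  duplicated stations, sealed route endpoints, unplaceable obstacle
  fields, over-tight meanders.

## Worked example

```{r example}
spec <- meander_spec(axis_length = 120, amplitude = 8, wavelength = 80,
                     width = 5, pool_reaches = list(c(30, 50)), seed = 7)
fx <- generate_site(spec)
cl <- extract_centerline(fx$banks, spacing_m = 1)
st <- extract_stations(fx$banks, fx$layers, cl)
pools <- detect_pools(st)
slope <- channel_gradient(263.36, 262.09, cl)
report <- assess_continuous(st, pools, cl, slope,
                            cwd_coverage = mean(c(
                              coverage_fraction(fx$banks$left_bank,
                                                fx$layers$woody_debris$left),
                              coverage_fraction(fx$banks$right_bank,
                                                fx$layers$woody_debris$right))))
report
```

## Known limitations

* Shapefile input is not supported; GeoJSON is the vector dialect.
* The depth model requires field-measured bed elevations and assumes a
  gradually varying bed.
* Bank stability is represented by erosion width alone, and the
  published thresholds were calibrated for non-mountain trout streams;
  transferring them to other settings needs re-calibration.
* Chemical and biological metrics are out of scope, as are braided
  channels and multi-drone missions.
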