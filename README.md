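# streamhab

Physical habitat health of small streams, assessed from drone-derived
vector data.

Wadeable trout streams are conventionally assessed by walking a handful
of tape-measured transects — slow, partly subjective, and blind to
anything that happens between transects. A drone survey followed by
feature digitisation yields the same physical quantities *continuously*
along the channel. `streamhab` implements the computational chain for
such a survey:

* **Flight planning** — boustrophedon (S-shaped) coverage routes at a
  high elevation for the whole site and a low elevation for the stream
  corridor, with line spacing `Δd = 2h·tan(FOV/2)·(1 − overlap)` for a
  target image overlap (75 % default, 90 % over the stream corridor),
  5 m obstacle buffers, optimal grid detours around obstacles
  (8-connected Dijkstra minimising length then turns, no corner
  cutting), collinear/line-of-sight route simplification, and a battery
  feasibility check (75 % of a 20-min battery, 30 s overhead).
* **Parameter extraction** — a medial-axis (equidistant) centerline
  between the banks; per-station wetted width W (shortest bank-to-bank
  chord, islands excluded), bank-top width BT, per-side erosion E,
  riparian buffer B and in-stream cover F widths, depth D
  (water surface minus interpolated bed), wetted fraction, a continuity
  velocity proxy ∝ 1/(W·D); sinuosity, bends (turning angle > 30° over a
  5 m window), channel gradient, and pool intervals (stations
  simultaneously deep, slow and free of white water).
* **MMI scoring** — nine metrics M1–M9 (gradient, buffer, bank
  stability, width/depth, sinuosity, flow status, woody debris,
  in-stream cover, bed forms). M1 selects the high- vs mild-gradient
  threshold system (slope > 0.02 m/m); M2–M9 are categorised
  excellent/good/fair/poor (scores 10/7.5/5/2.5), two-sided metrics
  contribute the mean of their side scores, and the total over M2–M9
  classifies the site (≥ 60 excellent, [45, 60) good, [30, 45) fair,
  < 30 poor). Three assessment modes: spatially continuous,
  n-transect, and vicinity (worst category within half a transect
  spacing of each transect).

A parametric sine-meander generator with analytically known ground truth
(`meander_spec()` / `generate_site()` / `degrade()`) makes the entire
pipeline testable offline.

## Worked example

Generate a 120 m meandering channel (amplitude 8 m, wavelength 80 m,
width 5 m) with one 20 m pool reach, extract the station series and
score it:

```r
library(streamhab)
spec <- meander_spec(axis_length = 120, amplitude = 8, wavelength = 80,
                     width = 5, pool_reaches = list(c(30, 50)), seed = 7)
fx <- generate_site(spec)
cl <- extract_centerline(fx$banks, spacing_m = 1)
st <- extract_stations(fx$banks, fx$layers, cl)
pools <- detect_pools(st)
pools
#>   s_start s_end
#> 1   29.79 50.64
slope <- channel_gradient(263.36, 262.09, cl)
assess_continuous(st, pools, cl, slope)
#> <habitat_report> continuous assessment, M-gradient channel (slope 0.0097)
#>   M2: left excellent (12), right excellent (12)
#>   M3: left excellent (0.1), right excellent (0.1)
#>   M4: good (9.476)
#>   M5: fair (1.092)
#>   M6: excellent (100)
#>   M7: poor (0)
#>   M8: excellent (12)
#>   M9: fair (15.91)
#>   total 60.00 -> excellent
```

The seeded 30–50 m pool is recovered within one station; the 12 m
riparian buffers score excellent on both banks (≥ 10 m), the sinuosity
of 1.09 is fair for a mild-gradient channel, the absence of woody debris
scores poor, and pools over 15.9 % of the stream length put bed forms in
the fair band. Each per-metric entry also carries the length-weighted
category distribution along the channel (`report$metrics$M2$left$pct_by_category`).

Route planning runs off the same site object:

```r
plan <- plan_route(fx$site, flight_config(), camera_model(), "high")
plan$time
```

A thin command-line front-end with subcommands `simulate`, `plan-route`,
`extract-params` and `assess` lives in `inst/cli/streamhab.R`.

## Package layout

| Area | Files |
|---|---|
| Domain types & config | `R/types.R` |
| GeoJSON / CSV / JSON / YAML I/O | `R/io.R` |
| Geometry kernel | `R/geometry.R` |
| Flight planning | `R/route.R`, `src/grid_search.cpp` |
| Centerline | `R/centerline.R` |
| Station measurements | `R/parameters.R` |
| MMI scoring | `R/mmi.R` |
| Synthetic sites | `R/simulate.R` |

See the vignette (`vignettes/stream-habitat-assessment.Rmd`) for the
models, their assumptions and the design decisions.
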