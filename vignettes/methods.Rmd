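---
title: "Pedestrian travel-time mapping: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedestrian travel-time mapping: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkshed)
```

## The problem and the approach

Straight-line distance to a clinic is a poor proxy for access on foot: it
ignores roads, terrain and water. `walkshed` models pedestrian access as a
least-cost-path problem on a fine (20 m) raster. The computation has two
stages. First, a **cost allocation surface** assigns every cell the time in
seconds a pedestrian needs to cross it, combining land cover, roads and
slope. Second, a **multi-source Dijkstra** computes, for every cell, the
minimum accumulated time to the nearest health facility.

Walking is the only mode modelled. In the settings this method targets,
most journeys to care are on foot, transport assets are scarce, and the
focus is on children: the default surfaces model an adult accompanied by a
child.

## Walking speeds

Speeds come from two lookup tables, both in km/h and both user-editable
CSVs.

* **Land cover** (`default_landcover_speeds()`): ten classes coded
  numerically. Open ground (grassland, cropland, sparse vegetation) walks
  at 3.0 km/h; obstructed cover (trees, shrubs, built-up) at 1.5 km/h;
  bare areas — predominantly dry riverbed in the source landscape — at
  1.15 km/h; open water at 1.0 km/h (used only when water is passable, see
  below); permanently flooded ground and nodata are barriers (`NA`).
* **Roads** (`default_road_speeds()`): the merged OpenStreetMap-style
  taxonomy, 3.5–5.0 km/h. Major tarmacked roads (motorway through primary)
  carry 5.0 km/h — pedestrians demonstrably walk along their shoulders and
  they are easier going than any land cover — so the model deliberately
  pushes walkers onto them. Unrecognised categories fall back to the
  `unknown` row (3.5 km/h) after fuzzy matching (normalised Levenshtein
  similarity, threshold 80/100; at 100 matching is exact after
  lower-casing and trimming). The threshold is a package choice: the
  matching step needs *some* cutoff, 80 tolerates spelling and case drift
  without conflating distinct categories.

The **child factor** (default 0.78) multiplies every speed, including
water. The value reflects field observations that adults accompanied by or
carrying children walk roughly 22% slower than unaccompanied adults.
Setting it to 1.0 produces adult surfaces. Because the factor is a single
multiplier, an entire child travel-time map equals the adult map divided by
0.78 — a property the test suite exercises end-to-end.

Speeds stay in km/h until cost assembly, where they convert to m/s
(5 km/h = 1.39 m/s); keeping the printed units in the tables makes them
auditable against their sources.

## Terrain

Slope is computed from a DEM in metres on the shared geographic grid.
Degree spacing converts to metres with a single factor, 111120 m/degree,
applied to both axes. This equirectangular approximation is only valid
near the equator; the package targets equatorial study areas and records
the convention rather than correcting for latitude. Gradients use central
differences in the interior and one-sided differences at the edges (so an
affine DEM yields its exact analytic slope everywhere — the property the
tests pin); cells whose elevation is missing, or whose stencil touches a
missing elevation, get `NA` slope.

Walking speed responds to slope through an empirical Gaussian-shaped
curve, `v(S) = 0.11 + exp(-(S+5)^2 / (2*30^2))` m/s, maximal on a gentle
downhill. Because a trip to a clinic is a return trip, the cell's
**slope impact** averages the uphill and downhill speeds and normalises by
the flat-ground speed; the result is symmetric in the sign of the slope,
equals 1 exactly on flat ground, and decreases monotonically. Slopes above
100% (45°) are treated as impassable outright — `NA` in the slope grid, the
impact grid and the cost surface, even where a road crosses the cell.

## Assembling the cost surfaces

Per cell: `seconds = cell_size_m / (speed_m_s * impact * child_factor)`,
with `cell_size_m` = 20 by default. Road speeds are laid down first
(all-touched rasterization, fastest category per cell), land-cover speeds
fill the remaining cells.

Two surfaces are built per scene:

* **water-blocked** — open water is `NA`. This is the primary surface:
  travel over water is forbidden.
* **water-passable** — open water carries a configured slow speed
  (default 1 km/h, a rough allowance for informal crossings).

A road cell overlapping water keeps its road speed in *both* surfaces:
the road-first overlay acts as bridge semantics. This is a package choice
where the behaviour was genuinely open; treating mapped roads across water
as crossable errs on the side of using mapped infrastructure.

### Rasterizing roads

A cell is marked iff a road segment intersects its **closed** square
("all-touched"). This guarantees a diagonal segment produces a gap-free
8-connected chain, so network connectivity survives rasterization — the
property that makes 20 m road rasters usable without anisotropic costs.
Within a cell, the fastest touching category wins (priority merge); the
merge can be disabled, in which case later features overwrite earlier
ones. Segments that graze a cell exactly at a corner touch all four closed
squares; this measure-zero configuration is rounding-sensitive and the
tests avoid asserting it.

## Facilities

Facility points are filtered by type (empty filter = nearest facility of
any type), clipped to a bounding box (a lightweight stand-in for an
administrative boundary polygon), and validated against the
**water-blocked** surface: a facility on an impassable cell (water, steep
slope, nodata) moves to one of its passable 8-neighbours chosen uniformly
at random under the run seed, or is removed if none is passable. Judging
passability on the blocked surface means facilities recorded in the middle
of a lake are relocated ashore or dropped, which is the intended reading
of "invalid locations". Every input facility appears exactly once in the
audit report (kept/moved/removed with a reason), and identical seeds give
bit-identical snapping.

## Least-cost travel time

The solver is a multi-source Dijkstra over the 8-connected grid
(implemented in C++ with a binary heap). The step cost between adjacent
cells i and j is `(t_i + t_j)/2 * d`, `d` = 1 for orthogonal and √2 for
diagonal moves in cell units — the geometric edge model under which a
straight orthogonal traverse of k uniform cells costs exactly `k * t`.
The suite checks the solver cell-for-cell (tolerance 1e-9) against an
independent explicit-graph Dijkstra built edge-by-edge with igraph, on
hundreds of random surfaces with `NA` patches.

**Two-pass rule.** Pass 1 runs on the blocked surface. Cells with finite
pass-1 time keep it — bit-identical, not recomputed. Cells infinite in
pass 1 (islands, and water itself) take their pass-2 value from the
passable surface; cells infinite in both become `NA`. Pass 2 is computed
from *all* sources: only pass-1-infinite cells consume its values, so
restricting sources would not change the observable output. Equal-cost
ties in Dijkstra need no tie-breaking because only the scalar time field
is published. Output maps are minutes; `+Inf` renders as GeoTIFF nodata.

## Numerical and format choices

* **GeoTIFF I/O** is implemented in the package: uncompressed little-endian
  single-band 64-bit float TIFF with ModelPixelScale/ModelTiepoint, a
  minimal EPSG:4326 GeoKey directory, and the GDAL nodata tag. Files are
  readable by standard GIS tools (a test cross-reads them with an
  independent TIFF library); the reader accepts integer and float rasters
  in either byte order but only uncompressed, square-cell, single-band
  data — the formats this pipeline produces and consumes. Projected
  coordinate systems, multi-band imagery and tiled/out-of-core rasters are
  out of scope.
* **Bilinear resampling** (used to bring a 30 m DEM onto the 20 m grid)
  covers the same extent, samples between input cell centres with edge
  replication, and is computed in the incremental form
  `a + f*(b - a)`, which is exact on constant fields and on affine fields
  away from the replicated border. Any interpolation touching an `NA`
  source cell yields `NA`: the package never fabricates elevations across
  DEM voids (the upstream DEM's void policy is unknown, so voids stay
  voids).
* **Vector roads** are read from GeoJSON (`tag` property). Facility tables
  and speed tables are CSV. Everything on disk is plain text apart from
  the rasters.
* Grids are square-celled; non-square inputs are rejected because the
  cost formula uses a single cell size.
* Speed-table child columns elsewhere in circulation are display-rounded
  (e.g. bare areas 1.15 × 0.78 = 0.897, sometimes printed 0.89); the
  engine keeps full precision throughout and only rounds for display.

## Synthetic scenes and what the tests show

The generators build deterministic toy scenes near the equator (origin
0.5°N, where the uniform degree-to-metre factor is appropriate): a uniform
plain with a central facility; an island enclosed by a water ring with the
only facility on the mainland; and seeded random landscapes (smoothed
random DEM scaled to a chosen relief, blocky land cover from the passable
classes, an L-shaped two-category road, random facilities). Default sizes
are 9–16 cells a side — large enough to exercise every branch (water
barriers, slope gating at high relief, snapping, type filtering) while
keeping the whole suite and the acceptance script fast; the solver-oracle
sweeps use up to 25×25 cells.

Passing on these scenes demonstrates the *mechanics* — the formulas, the
barrier logic, the solver, determinism — not realism: real land-cover
mosaics, real road topologies, facility mislocation patterns and DEM noise
are all richer than the generators. Country-scale results therefore depend
on input data quality (land-cover classification accuracy, road
completeness) in ways these tests cannot certify.

## Known limitations

* Isotropic costs: crossing a cell costs the same in every direction; at
  20 m resolution directional road effects are negligible, which is what
  justifies rasterizing roads at all.
* The nearest-facility assumption: households demonstrably bypass the
  nearest facility for many reasons; the maps measure potential, not
  realised, access.
* The uniform 111120 m/degree factor degrades away from the equator.
* No motorised modes, catchment maps or population weighting.
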