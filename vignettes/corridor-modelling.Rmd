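---
title: "Modelling pollinator corridors from pesticide toxic loads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pollinator corridors from pesticide toxic loads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agcorridors)
```

## The model

`agcorridors` models landscape connectivity for flying, pollinating
insects across an intensively farmed valley. Its central assumption is
that resistance to movement is driven largely by pesticide lethality: a
land class that receives many honey-bee contact-LD50 doses per acre is
harder for insects to traverse, whether through direct mortality or
sublethal effects. The pipeline has four stages.

**1. Toxic load.** For each land class and year, reported pesticide use in
pounds is converted to micrograms (1 lb = 453,592,370 ug), divided by the
chemical's contact LD50 (ug/bee) to give lethal doses, divided by the
class acreage, and summed over chemicals:

$$ L_{c,y} \;=\; \sum_{i} \frac{453{,}592{,}370 \cdot \text{lbs}_{i,c,y}}
   {\mathrm{LD50}_i \cdot A_c} \quad \text{[LD50 doses acre}^{-1}\text{]} $$

Interannual variation over the three reporting years is folded into three
scenarios per class: low, medium and high are the minimum, median and
maximum of the three annual loads. A class reported in some years but not
others gets load 0 for the silent years, since absence from use reporting
means no reported application. Structural pest control records are
excluded (their risk to pollinators is unknown), and seed-treatment loads
are not modelled (they are absent from use reporting).

**2. Resistance.** Loads are translated to integer resistance by
anchoring to a landscape-genetics result: urban land is about eight times
more resistant to bumble-bee movement than natural land (genetic-model
resistances 0.8 - the mean of the supported 0.7-0.9 range - versus 0.1).
With natural land at the isolation-by-distance baseline of 1, a class's
resistance is extrapolated linearly in its load relative to the urban
load,

$$ R_c \;=\; \mathrm{clamp}\!\left(\Big\lfloor \tfrac{L_c}{L_\text{urban}}
   \cdot R_\text{urban} + \tfrac12 \Big\rfloor,\, 1,\, 100\right), $$

with per-level urban anchors 7/8/9. Rounding is half-up; 100 means a cell
one hundred times harder to traverse than baseline. Classes whose
resistance is not pesticide-driven (agricultural margins, urban
greenspace, bare soil, open water) carry expert-assigned values, shipped
verbatim from the published table; an `Other` class takes the rounded
mean of all computed crop resistances.

**3. Cost distance.** Least-cost corridors are computed with Dijkstra's
algorithm on the 8-connected cell graph - the standard GIS Cost Distance
operation. A move between neighbouring cells costs the mean of their two
resistances times the move length (1 cell orthogonally, sqrt(2)
diagonally), so accumulated costs are in "cells traversed x cost" units.
A backlink grid records each cell's predecessor direction and is followed
to trace paths. Nodata cells are impassable.

**4. The experiment.** Endpoints are placed by arc length along west and
east perimeter lines, paired within a Euclidean distance buffer, and each
west point's cost surface is traced to all its paired east points. To
absorb endpoint placement noise the process is repeated over iterations
with endpoints jittered uniformly within a disc; iteration 1 keeps the
original points so the canonical configuration is always represented.
The factorial crosses three margin treatments - *restored* (margins
recoded to natural), *current*, and *none* (margins absorbed into the
nearest crop parcel) - with the three resistance levels, nine scenarios
in all. Each scenario run is summarised by four statistics: total path
length, unique (non-overlapping) path length inside the inner study area,
mean distance from inner cells to the nearest path, and the mean number
of convergent paths per occupied inner cell; plus the fraction of path
length common to one, two or all three resistance levels, and the
land-cover composition of paths.

## The synthetic landscape

The study's real inputs (crop maps, coastal and national land-cover
products, a public pesticide-use portal) are proprietary to assemble, so
the package ships a seeded generator that emulates their structure: an
inner agricultural matrix of axis-aligned rectangular crop parcels, each
ringed by 1-cell (30 m) linear margins; scattered urban patches with
greenspace fringes and impervious cores; small natural remnants, water
bodies and bare soil; and a low-resistance natural/grassland perimeter
ring from which corridor endpoints are drawn.

Default conditions follow the published landscape description where one
exists: 30 m cells; inner-area fractions of about 65% crops, 9% linear
margins (the observed interior margin share is just under 9%), 10% urban,
4% natural remnants, 1% water. Parcels are placed on a jittered lattice
with 1-cell gaps so neighbouring parcels *share* a margin strip; a pure
rejection-sampling placement of isolated rectangles was tried first and
discarded, because random sequential packing of rectangles saturates near
55% coverage and cannot reach the observed crop share, and isolated
rings double-count margins (~20% margin share). Lattice placement with
shared margins reaches both targets simultaneously, and still yields the
visually rectangular, road-grid-aligned field geometry of real valley
agriculture. Parcel sides default to 16-24 cells (480-720 m), the scale
at which the margin share lands at its target.

Default application intensities are calibrated so each crop's
medium-scenario load sits at the magnitude implied by its published
medium resistance (a class with medium resistance R receives R/8 times
the urban intensity of 0.12 lbs/acre/yr across a fixed six-chemical
mix); interannual variation is lognormal with CV 0.3. Thus the synthetic
crops span the published range from effectively untreated rice to
heavily treated citrus.

What the generator does **not** emulate: real parcel geometry and crop
autocorrelation, the NDVI-based separation of urban subclasses,
conservation-land overlays, rivers as connected linear water features,
and the valley's 400+ km extent. Tests passing on synthetic landscapes
therefore demonstrate that the machinery is correct and that the
directional conclusions are insensitive to endpoint noise - not that the
absolute published numbers (million-km path totals, 10.4 km mean
distances) are recovered; those depend on the full-valley rasters.

## Numerical choices

* **Seeding.** One master seed; every stage derives child seeds through a
  documented integer-folding scheme (`child_seed()`), so any stage can be
  re-run independently and bit-identically. Jitter seeds depend on
  (seed, iteration, side, point index) but *not* on the scenario, giving
  all nine scenarios identical endpoint realizations - a paired design.
* **Tie-breaking.** All ties are resolved by the lower row-major flat
  cell index: in the Dijkstra settle queue, in equal-cost predecessor
  choice, and in nearest-crop assignment when margins are eliminated.
  Traced paths are therefore reproducible across platforms.
* **Rounding.** Resistance rounding is half-up (11.5 rounds to 12), with
  floor 1 and cap 100.
* **Per-level anchoring.** Whether the published analysis scaled each
  level's loads against that level's urban load or always against the
  medium urban load is not stated. The default scales per level with
  anchors 7/8/9, keeping the urban row self-consistent; because the
  urban load's interannual spread can exceed a crop's, this can produce
  non-monotone low/medium/high triples, which are sorted into order with
  a warning so the table invariant always holds.
  `build_resistance_table(anchor_mode = "medium")` switches to
  medium-load anchoring, under which monotonicity is automatic.
* **Moves, not cells.** Path overlap (unique length, commonality) is
  defined on undirected cell-to-cell moves rather than cells, so two
  paths crossing at a point share no corridor length. A move belongs to
  the inner area when both its endpoint cells do (equivalently, when its
  midpoint lies strictly inside; boundary-straddling moves, whose
  midpoint sits exactly on the inner boundary, count as outside).
  Composition attributes each move to the cell it *enters*, against the
  **original** land cover, so restored or eliminated margins are still
  reported under their original margin identity - matching how the
  reference analysis reports a nonzero margin share even in the
  no-margins scenario.
* **Commonality extent.** Whether the published percentage-in-common is
  computed inner-only or over the full extent is not stated; both are
  available (`inner_mask` argument) and the full extent is the default.
* **Degenerate inputs.** Empty path sets give total length 0 but
  *missing* (not 0) distance-to-path and convergence; unreachable
  west-east pairs are dropped with a count; sources on nodata are
  dropped with a warning and error only when none remain.
* **Aggregation.** Metrics are computed per iteration and then averaged
  (mean and sd across iterations); the reference reports averages
  without stating the order.

## Worked example at desk scale

The default experiment uses the full synthetic landscape (200 x 300
cells at 30 m, i.e. 9 x 6 km) with endpoint spacing and jitter radius of
600 m and five iterations - the same spacing-to-extent ratio as the
published valley-scale design (5 km spacing on a hundreds-of-km
perimeter), chosen so the nine-scenario factorial completes in under a
minute on one CPU.

```{r experiment, eval = FALSE}
ls <- generate_landscape(landscape_config(), seed = 1)
tabs <- generate_pesticide_tables(ls$grid, pesticide_config(), seed = 1)
scen <- collapse_to_scenarios(
  toxic_load_annual(tabs$use_records, tabs$ld50, tabs$acreage))
rtable <- build_resistance_table(scen)
cfg <- run_config(point_spacing_m = 600, jitter_radius_m = 600,
                  n_iterations = 5, seed = 1)
exp <- run_experiment(ls$grid, ls$masks, rtable, cfg)
subset(exp$summary, stat == "mean")
```

On this landscape the factorial reproduces the reference study's
directional pattern - restored margins yield several-fold more unique
inner path length, several-fold smaller mean distance to a path, fewer
convergent paths and shorter total path length than the current and
no-margins treatments, which differ from each other far less; margins
carry the majority of restored-scenario path length but well under 1% of
current-scenario path length; and most path length is common to all
three resistance levels. The acceptance tests assert exactly these
orderings rather than the study's absolute valley-scale values.

## Limitations

Resistance here is a coarse, assumption-laden construct: a single
surface cannot represent the range of body sizes and behaviours of real
pollinators; urban pesticide use is under-reported, so urban loads are
underestimates; seed treatments are invisible to use reporting; the land
cover is static while real crops rotate. The cost-distance model assumes
cost accrues cell by cell, which suits insects that move between
adjacent 30 m cells over generations, not strong long-distance
dispersers. These caveats are inherited from the modelling framework the
package implements; the package adds one of its own - its landscapes are
synthetic, and any application to a real region must supply real land
cover, use records and acreage through the documented file formats.
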