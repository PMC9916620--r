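# agcorridors

Least-cost corridor modelling for pollinating insects across intensively
farmed landscapes, with movement resistance estimated from pesticide
lethality.

Agricultural valleys are hostile terrain for bees and butterflies: crops
are treated with insecticides of very different toxicity, natural habitat
is scarce, and what remains is fragmented. Yet the narrow uncultivated
strips along field edges — drainage ditches, weedy borders, hedgerow
candidates — collectively cover more area than most single crops, and
form a near-continuous lattice through the agricultural matrix. This
package asks, quantitatively: *how much would restoring (or losing) those
agricultural margins change landscape connectivity for pollinators?* It
is written for landscape ecologists and restoration practitioners who
want a reproducible, scriptable version of this analysis, free of any
proprietary GIS inputs.

## The model

1. **Toxic load.** Reported pesticide use is converted to honey-bee
   contact-LD50 doses per acre per year for every land class:

   L(c,y) = Σᵢ 453,592,370 · lbsᵢ / (LD50ᵢ · A(c))

   Three reporting years collapse to low/medium/high scenario loads
   (min/median/max).

2. **Resistance.** Loads map linearly to integer resistance anchored at
   urban = 8 × natural (a landscape-genetics estimate for bumble bees),
   with natural land at the isolation-by-distance baseline 1 and a cap
   of 100: R(c) = round(L(c)/L(urban) × 8), per-level anchors 7/8/9.
   Expert values cover the classes pesticides cannot rank (margins,
   water, bare soil, urban greenspace).

3. **Corridors.** Dijkstra cost-distance on the 8-connected grid (move
   cost = mean resistance of the two cells × move length) with backlink
   tracing yields least-cost paths between jittered endpoint pairs on
   the western and eastern perimeters, over a 3 × 3 factorial of margin
   treatment (restored / current / none) × resistance level
   (low / medium / high).

4. **Metrics.** Total path length, unique (non-overlapping) inner path
   length, mean distance to the nearest path, mean convergent paths per
   cell, commonality of corridors across resistance levels, and the
   land-cover composition of paths.

A seeded synthetic-landscape generator (rectangular crop parcels ringed
by 1-cell margins, urban patches, water, natural perimeter) stands in
for the original proprietary land-cover stack, so the entire pipeline
runs, and is tested, without any downloads.

## Worked example

```r
library(agcorridors)

ls     <- generate_landscape(landscape_config(), seed = 1)   # 200 x 300 @ 30 m
tabs   <- generate_pesticide_tables(ls$grid, pesticide_config(), seed = 1)
scen   <- collapse_to_scenarios(
            toxic_load_annual(tabs$use_records, tabs$ld50, tabs$acreage))
rtable <- build_resistance_table(scen)
cfg    <- run_config(point_spacing_m = 600, jitter_radius_m = 600,
                     n_iterations = 5, seed = 1)
exp    <- run_experiment(ls$grid, ls$masks, rtable, cfg)
subset(exp$summary, stat == "mean" & level == "medium")
```

```
 margin_scenario  level n_paths total_path_length_km
         current medium      81                  948
            none medium      81                  946
        restored medium      81                  799
 unique_path_length_inner_km mean_distance_to_path_km mean_convergent_paths
                        14.1                    1.010                 19.97
                        14.2                    1.007                 19.64
                       110.3                    0.165                  6.89
```

Restoring margins turns a handful of heavily shared corridors into a
spread-out network: ~8× more unique path length inside the agricultural
interior, cells ~6× closer to the nearest corridor, one third the path
convergence, and shorter (more direct) routes — while eliminating
margins barely differs from the status quo. Margins carry 53% of
restored-scenario path length versus ~0.1–0.2% otherwise
(`exp$composition`). This is the directional fingerprint of margin
restoration; the absolute numbers scale with landscape extent.

The same stages are scriptable from a shell via
`inst/scripts/corridors.R` (subcommands `simulate`, `toxload`, `resist`,
`corridors`, `metrics`, `run-all`), every stage reading and writing
plain files (ESRI ASCII grids, GeoJSON, CSV, a JSON run manifest).

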