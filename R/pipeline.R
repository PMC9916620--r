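#' Run the full corridor-modelling pipeline
#'
#' Executes every stage end to end and persists all intermediates: generate
#' the synthetic landscape and pesticide tables, estimate annual and
#' scenario toxic loads, build the resistance table, run the margin x
#' resistance factorial corridor experiment, and compute the connectivity
#' metrics. Two invocations with the same master seed produce byte-identical
#' outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed for every source of randomness.
#' @param landscape a [landscape_config()].
#' @param pesticides a [pesticide_config()].
#' @param run a [run_config()] (its `seed` is replaced by `seed`).
#' @param margins,levels factor levels of the experiment.
#' @param write_surfaces also export the nine accumulated resistance grids.
#' @return invisibly, a list with the landscape, tables, experiment results
#'   and the manifest.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         landscape = landscape_config(),
                         pesticides = pesticide_config(),
                         run = run_config(),
                         margins = c("restored", "current", "none"),
                         levels = c("low", "medium", "high"),
                         write_surfaces = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run$seed <- seed
  out <- function(...) file.path(out_dir, paste0(...))
  artifacts <- character()
  keep <- function(p) { artifacts <<- c(artifacts, p); p }

  ls <- generate_landscape(landscape, seed)
  write_grid(ls$grid, keep(out("landcover.asc")))
  write_ascii_grid(ls$masks$inner + 0L, keep(out("inner_mask.asc")),
                   ls$grid$cell_size, ls$grid$origin)
  write_lines_geojson(list(west = ls$masks$west_line,
                           east = ls$masks$east_line),
                      keep(out("perimeter_lines.geojson")))
  write.csv(ls$grid$classes, keep(out("land_classes.csv")),
            row.names = FALSE)

  tables <- generate_pesticide_tables(ls$grid, pesticides, seed)
  write.csv(tables$use_records, keep(out("use_records.csv")),
            row.names = FALSE)
  write.csv(tables$ld50, keep(out("ld50.csv")), row.names = FALSE)
  write.csv(tables$acreage, keep(out("acreage.csv")), row.names = FALSE)

  annual <- toxic_load_annual(tables$use_records, tables$ld50,
                              tables$acreage)
  write.csv(annual, keep(out("toxic_load.csv")), row.names = FALSE)
  scen <- collapse_to_scenarios(annual)
  write.csv(scen, keep(out("toxic_load_scenarios.csv")), row.names = FALSE)

  rtable <- build_resistance_table(scen, urban_class = pesticides$urban_class)
  write.csv(rtable, keep(out("resistance_table.csv")), row.names = FALSE)

  if (write_surfaces) {
    for (m in margins) {
      g <- apply_margin_scenario(ls$grid, m)
      for (lv in levels)
        write_grid(rasterize_resistance(g, rtable, lv, m),
                   keep(out("resist_", m, "_", lv, ".asc")))
    }
  }

  exp <- run_experiment(ls$grid, ls$masks, rtable, run, margins, levels)
  for (key in names(exp$paths))
    write_paths_geojson(exp$paths[[key]],
                        keep(out("paths_", key, ".geojson")))
  for (key in names(exp$paths)) {
    sub <- exp$metrics[exp$metrics$margin_scenario ==
                         exp$paths[[key]]$margin_scenario &
                       exp$metrics$level == exp$paths[[key]]$level, ]
    write.csv(sub, keep(out("metrics_", key, ".csv")), row.names = FALSE)
  }
  write.csv(exp$summary, keep(out("metrics_summary.csv")),
            row.names = FALSE)
  write.csv(exp$composition, keep(out("composition.csv")),
            row.names = FALSE)

  manifest <- write_manifest(out("manifest.json"), seed,
                             list(landscape = landscape,
                                  pesticides = pesticides, run = run),
                             artifacts)
  invisible(list(landscape = ls, tables = tables, annual = annual,
                 scenario_loads = scen, resistance_table = rtable,
                 experiment = exp, manifest = manifest))
}
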