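#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange in the ESRI ASCII grid format (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value` header
#' followed by rows north to south). Values, nodata and the geotransform
#' round-trip losslessly for integer grids. Coordinates are assumed to be
#' in a projected CRS in metres; grids whose header looks geographic
#' (cellsize < 0.01, the scale of degrees) are rejected.
#'
#' @param values numeric or integer matrix (`NA` = nodata; row 1 = north).
#' @param path file path.
#' @param cell_size cell edge in metres.
#' @param origin lower-left corner `c(x, y)`.
#' @param nodata nodata value written to the file.
#' @return `read_ascii_grid()`: list with `values`, `cell_size`, `origin`,
#'   `nodata`. `write_ascii_grid()`: the path, invisibly.
#' @export
write_ascii_grid <- function(values, path, cell_size, origin = c(0, 0),
                             nodata = -9999) {
  m <- values
  m[is.na(m)] <- nodata
  header <- c(
    paste("ncols", ncol(values)), paste("nrows", nrow(values)),
    paste("xllcorner", format(origin[1], scientific = FALSE)),
    paste("yllcorner", format(origin[2], scientific = FALSE)),
    paste("cellsize", format(cell_size, scientific = FALSE)),
    paste("NODATA_value", format(nodata, scientific = FALSE))
  )
  rows <- apply(m, 1, paste, collapse = " ")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  header <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(header)))
    stop("not an ESRI ASCII grid: missing ",
         paste(setdiff(need, names(header)), collapse = ", "))
  if (any(c("xllcenter", "yllcenter") %in% names(header)))
    stop("cell-centre referenced ASCII grids are not supported")
  if (header$cellsize < 0.01)
    stop("cellsize ", header$cellsize, " looks like degrees; ",
         "a projected CRS in metres is required")
  nodata <- header[["nodata_value"]]
  if (is.null(nodata)) {
    warning("no NODATA_value tag; assuming -9999")
    nodata <- -9999
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != header$nrows * header$ncols)
    stop("expected ", header$nrows * header$ncols, " values, got ",
         length(vals))
  m <- matrix(vals, nrow = header$nrows, ncol = header$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  list(values = m, cell_size = header$cellsize,
       origin = c(header[["xllcorner"]] %||% 0,
                  header[["yllcorner"]] %||% 0),
       nodata = nodata)
}

#' Write a land-cover grid, mask, or resistance grid to disk
#'
#' @param grid a [land_grid()], `resist_grid`, or logical mask matrix.
#' @param path output `.asc` path.
#' @param ... passed through to [write_ascii_grid()] for plain matrices.
#' @return the path, invisibly.
#' @export
write_grid <- function(grid, path, ...) {
  if (inherits(grid, "land_grid")) {
    write_ascii_grid(grid$codes, path, grid$cell_size, grid$origin,
                     grid$nodata)
  } else if (inherits(grid, "resist_grid")) {
    write_ascii_grid(grid$values, path, grid$cell_size, grid$origin)
  } else {
    write_ascii_grid(grid, path, ...)
  }
}

#' Export least-cost paths as GeoJSON LineStrings
#'
#' One feature per path, geometry through cell centres, with properties
#' `source_id`, `dest_id`, `iteration`, `margin_scenario`, `level`,
#' `total_cost`, `length_km`.
#'
#' @param set an `lcp_set`.
#' @param path output `.geojson` path.
#' @return the path, invisibly.
#' @export
write_paths_geojson <- function(set, path) {
  geom <- list(cell_size = set$cell_size, origin = set$origin,
               codes = matrix(0L, set$dim[1], set$dim[2]))
  features <- lapply(set$paths, function(p) {
    xy <- cell_center_xy(geom, p$cells[, 1], p$cells[, 2])
    list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = unname(split(unname(xy), row(xy)))),
      properties = list(
        source_id = p$source_id %||% NA, dest_id = p$dest_id %||% NA,
        iteration = p$iteration %||% 1L,
        margin_scenario = p$margin_scenario %||% set$margin_scenario,
        level = p$level %||% set$level,
        total_cost = p$total_cost, length_km = p$length_m / 1000)
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_paths_geojson
#' @param cell_size,origin,dim grid geometry used to map coordinates back
#'   to cells when reading.
#' @export
read_paths_geojson <- function(path, cell_size, origin, dim) {
  gj <- jsonlite::read_json(path)
  geom <- list(cell_size = cell_size, origin = origin,
               codes = matrix(0L, dim[1], dim[2]))
  paths <- lapply(gj$features, function(feat) {
    xy <- do.call(rbind, lapply(feat$geometry$coordinates, unlist))
    cells <- cell_at_xy(geom, xy[, 1], xy[, 2])
    pr <- feat$properties
    structure(list(cells = unname(cells), total_cost = pr$total_cost,
                   length_m = pr$length_km * 1000,
                   source_id = pr$source_id, dest_id = pr$dest_id,
                   iteration = pr$iteration %||% 1L,
                   margin_scenario = pr$margin_scenario, level = pr$level),
              class = "lcp_path")
  })
  first <- if (length(paths)) paths[[1]] else NULL
  structure(list(paths = paths, cell_size = cell_size, origin = origin,
                 dim = dim,
                 margin_scenario = first$margin_scenario %||% "current",
                 level = first$level %||% "medium",
                 n_pairs = length(paths), n_dropped = 0L),
            class = "lcp_set")
}

#' @rdname write_paths_geojson
#' @param lines named list of two-column coordinate matrices (e.g. the
#'   study perimeter lines).
#' @export
write_lines_geojson <- function(lines, path) {
  features <- lapply(names(lines), function(nm) {
    xy <- lines[[nm]]
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = unname(split(unname(xy), row(xy)))),
         properties = list(name = nm))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the run manifest
#'
#' A JSON record sufficient to re-run any stage bit-identically: the full
#' configuration echo, master seed, per-stage child seeds, package version,
#' and an inventory of output artifacts with MD5 digests.
#'
#' @param path output path.
#' @param seed master seed.
#' @param configs named list of configuration objects (echoed verbatim).
#' @param artifacts character vector of output file paths.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, seed, configs, artifacts = character()) {
  digests <- if (length(artifacts))
    as.list(tools::md5sum(artifacts)) else NULL
  manifest <- list(
    package = "agcorridors",
    version = as.character(utils::packageVersion("agcorridors")),
    master_seed = seed,
    child_seeds = list(landscape = child_seed(seed, 1),
                       pesticides = child_seed(seed, 2)),
    configs = lapply(configs, unclass),
    artifacts = digests
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}

#' Read a pipeline configuration file
#'
#' YAML with optional top-level blocks `landscape`, `pesticides`, and
#' `run`, whose entries override the corresponding defaults of
#' [landscape_config()], [pesticide_config()] and [run_config()].
#'
#' @param path YAML file path.
#' @return list with `landscape`, `pesticides`, `run` config objects.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  build <- function(fn, args) do.call(fn, args %||% list())
  list(landscape = build(landscape_config, raw$landscape),
       pesticides = build(pesticide_config, raw$pesticides),
       run = build(run_config, raw$run))
}
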