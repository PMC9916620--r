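#' Land-cover grid objects
#'
#' A `land_grid` is the package's raster container: an integer matrix of
#' land-cover class codes plus the georeferencing needed to place cell
#' centres in a projected (metre) coordinate system, and a class table
#' mapping every code to a name and a functional role. Roles drive the
#' margin experiments and the land-cover composition metric.
#'
#' Coordinate convention: cells are indexed `(row, col)` with row 1 at the
#' top (north). The flat row-major 0-based index `(row-1)*ncol + (col-1)`
#' is used wherever deterministic tie-breaking is required. The centre of
#' cell `(i, j)` lies at `origin + ((j - 0.5), (nrow - i + 0.5)) * cell_size`
#' with `origin` the lower-left corner of the grid.
#'
#' @param codes integer matrix of class codes (`NA` = nodata).
#' @param cell_size cell edge length in metres (positive).
#' @param origin numeric length-2, x/y of the lower-left grid corner.
#' @param classes data frame with columns `code`, `name`, `role`. Roles are
#'   one of `crop`, `margin`, `natural`, `grassland`, `urban`,
#'   `urban_greenspace`, `urban_impervious`, `bare`, `water`, `other`.
#' @param nodata integer nodata code used when the grid is written to disk.
#' @return an object of class `land_grid`.
#' @export
land_grid <- function(codes, cell_size, origin = c(0, 0), classes,
                      nodata = -9999L) {
  storage.mode(codes) <- "integer"
  g <- structure(
    list(codes = codes, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), classes = classes,
         nodata = as.integer(nodata)),
    class = "land_grid"
  )
  validate_land_grid(g)
  g
}

.known_roles <- c("crop", "margin", "natural", "grassland", "urban",
                  "urban_greenspace", "urban_impervious", "bare", "water",
                  "other")

#' Validate a land-cover grid
#'
#' Checks the structural invariants of a [land_grid()]: positive cell size,
#' at least 2 x 2 cells, every non-nodata code present in the class table
#' with a known role, and (when margins are present at the default 1-cell
#' width) every margin cell 8-adjacent to at least one crop cell.
#'
#' @param grid a `land_grid`.
#' @param check_margins logical; also check margin/crop adjacency.
#' @return `grid`, invisibly; errors on violation.
#' @export
validate_land_grid <- function(grid, check_margins = FALSE) {
  stopifnot(is.matrix(grid$codes))
  if (grid$cell_size <= 0) stop("cell_size must be > 0")
  if (nrow(grid$codes) < 2 || ncol(grid$codes) < 2)
    stop("grid must be at least 2 x 2 cells")
  cl <- grid$classes
  if (!all(c("code", "name", "role") %in% names(cl)))
    stop("class table must have columns code, name, role")
  bad_role <- setdiff(cl$role, .known_roles)
  if (length(bad_role))
    stop("unknown class role(s): ", paste(bad_role, collapse = ", "))
  used <- unique(grid$codes[!is.na(grid$codes)])
  unmapped <- setdiff(used, cl$code)
  if (length(unmapped))
    stop("codes without a class-table entry: ", paste(unmapped, collapse = ", "))
  if (check_margins && !all(margin_has_crop_neighbour(grid)))
    stop("margin cell(s) without an adjacent crop cell")
  invisible(grid)
}

role_matrix <- function(grid) {
  lookup <- setNames(grid$classes$role, grid$classes$code)
  m <- matrix(lookup[as.character(grid$codes)], nrow(grid$codes))
  m
}

#' @rdname validate_land_grid
#' @return `margin_has_crop_neighbour()`: logical vector, one entry per
#'   margin cell, `TRUE` when the cell touches a crop cell (8-neighbourhood).
#' @export
margin_has_crop_neighbour <- function(grid) {
  roles <- role_matrix(grid)
  is_m <- !is.na(roles) & roles == "margin"
  is_c <- !is.na(roles) & roles == "crop"
  idx <- which(is_m, arr.ind = TRUE)
  if (nrow(idx) == 0) return(logical(0))
  nr <- nrow(roles); nc <- ncol(roles)
  apply(idx, 1, function(rc) {
    r <- rc[1]; c <- rc[2]
    rr <- max(1, r - 1):min(nr, r + 1)
    cc <- max(1, c - 1):min(nc, c + 1)
    any(is_c[rr, cc])
  })
}

#' @export
print.land_grid <- function(x, ...) {
  cat(sprintf("<land_grid> %d x %d cells at %g m (%.1f x %.1f km)\n",
              nrow(x$codes), ncol(x$codes), x$cell_size,
              ncol(x$codes) * x$cell_size / 1000,
              nrow(x$codes) * x$cell_size / 1000))
  tab <- table(role_matrix(x))
  frac <- round(100 * tab / sum(tab), 1)
  cat("  roles:", paste0(names(tab), " ", frac, "%", collapse = ", "), "\n")
  invisible(x)
}

#' Default crop classes for the synthetic landscape
#'
#' Eight crop groups spanning the published range of pesticide intensity,
#' from effectively untreated (rice) to heavily treated (citrus). Names
#' match the packaged resistance table so synthetic grids can be rasterized
#' against it directly.
#'
#' @return character vector of crop class names.
#' @export
default_crop_classes <- function() {
  c("Rice", "Corn, Sorghum and Sudan", "Wheat",
    "Alfalfa and Alfalfa Mixtures", "Tomatoes", "Grapes", "Almonds",
    "Citrus")
}

base_class_table <- function(crop_classes) {
  base <- data.frame(
    code = 1:9,
    name = c("Natural", "Grassland", "Agricultural Margin", "Urban",
             "Urban Greenspace", "Urban Impervious", "Bare Soil", "Water",
             "Other"),
    role = c("natural", "grassland", "margin", "urban", "urban_greenspace",
             "urban_impervious", "bare", "water", "other"),
    stringsAsFactors = FALSE
  )
  if (length(crop_classes)) {
    base <- rbind(base, data.frame(code = 10L + seq_along(crop_classes),
                                   name = crop_classes, role = "crop",
                                   stringsAsFactors = FALSE))
  }
  base
}

#' Synthetic-landscape configuration
#'
#' Parameters of the seeded landscape generator. The defaults emulate the
#' structure of an intensively farmed valley floor at 30 m resolution: an
#' inner agricultural matrix of rectangular crop parcels separated by
#' 1-cell linear margins (about 9% of the inner area), scattered urban
#' patches with greenspace fringes and impervious cores, small natural
#' remnants and water bodies, all ringed by a low-resistance
#' natural/grassland perimeter from which corridor endpoints are drawn.
#'
#' @param nrow,ncol grid dimensions in cells.
#' @param cell_size cell edge in metres.
#' @param origin lower-left corner coordinates (projected metres).
#' @param ring_width width in cells of the natural/grassland outer ring.
#' @param crop_classes character vector of crop class names.
#' @param parcel_side_range min/max crop-parcel side, in cells.
#' @param margin_width margin ring width in cells (the margin-adjacency
#'   invariant is guaranteed at the default width 1).
#' @param target_crop_fraction,target_urban_fraction inner-area fractions
#'   at which parcel/urban placement stops.
#' @param target_margin_fraction intended inner-area margin fraction; the
#'   realized value emerges from parcel geometry and is validated against
#'   this target (within 3 percentage points) rather than enforced.
#' @param natural_inner_fraction,water_fraction,bare_fraction inner-area
#'   fractions of natural remnants, water bodies, and bare soil.
#' @param urban_side_range,natural_side_range,water_side_range patch side
#'   ranges, in cells.
#' @return a list of class `landscape_config`.
#' @export
landscape_config <- function(nrow = 200, ncol = 300, cell_size = 30,
                             origin = c(0, 0), ring_width = 12,
                             crop_classes = default_crop_classes(),
                             parcel_side_range = c(16, 24),
                             margin_width = 1,
                             target_crop_fraction = 0.65,
                             target_margin_fraction = 0.09,
                             target_urban_fraction = 0.10,
                             natural_inner_fraction = 0.04,
                             water_fraction = 0.01,
                             bare_fraction = 0.005,
                             urban_side_range = c(8, 16),
                             natural_side_range = c(6, 12),
                             water_side_range = c(4, 8)) {
  cfg <- as.list(environment())
  class(cfg) <- "landscape_config"
  cfg
}

sample_side <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1)
}

# Partition the parcel-eligible area into a jittered lattice of blocks:
# vertical strips of sampled width, each cut into blocks of sampled height,
# with 1-cell gaps between blocks so that each parcel keeps an unclipped
# margin ring that is shared with its neighbours.
make_blocks <- function(rows, cols, side_range, gap) {
  blocks <- list()
  c0 <- cols[1]
  while (c0 + side_range[1] - 1 <= cols[2]) {
    w <- min(sample_side(side_range), cols[2] - c0 + 1)
    r0 <- rows[1]
    while (r0 + side_range[1] - 1 <= rows[2]) {
      h <- min(sample_side(side_range), rows[2] - r0 + 1)
      blocks[[length(blocks) + 1]] <- c(r0, r0 + h - 1, c0, c0 + w - 1)
      r0 <- r0 + h + gap
    }
    c0 <- c0 + w + gap
  }
  blocks
}

paint_margin_ring <- function(codes, rect, width, margin_code, paintable) {
  nr <- nrow(codes); nc <- ncol(codes)
  rr <- max(1, rect[1] - width):min(nr, rect[2] + width)
  cc <- max(1, rect[3] - width):min(nc, rect[4] + width)
  for (r in rr) for (c in cc) {
    inside <- r >= rect[1] && r <= rect[2] && c >= rect[3] && c <= rect[4]
    if (!inside && codes[r, c] %in% paintable) codes[r, c] <- margin_code
  }
  codes
}

#' Generate a synthetic agricultural landscape
#'
#' Deterministically builds a [land_grid()] and its study masks from a
#' [landscape_config()] and a seed. Crop parcels are axis-aligned
#' rectangles placed on a jittered lattice with 1-cell gaps (so adjacent
#' parcels share a linear margin, which is what keeps the realized margin
#' fraction near the observed ~9% of the inner area); each parcel is ringed
#' by margin cells. Unused lattice blocks host urban patches, natural
#' remnants, water bodies and bare soil, so none of them ever severs a
#' margin from its parcel. The outer ring is natural (outer half) and
#' grassland (inner half).
#'
#' @param config a [landscape_config()].
#' @param seed integer master seed; all placement randomness derives from
#'   `child_seed(seed, 1)`.
#' @return a list with elements `grid` (a `land_grid`) and `masks` (a list
#'   with logical matrix `inner`, and two-column coordinate matrices
#'   `west_line` and `east_line` running along the perimeter ring).
#' @export
#' @examples
#' ls <- generate_landscape(landscape_config(nrow = 60, ncol = 80,
#'                                           ring_width = 6), seed = 1)
#' ls$grid
generate_landscape <- function(config = landscape_config(), seed = 1) {
  cfg <- config
  nr <- cfg$nrow; nc <- cfg$ncol; ring <- cfg$ring_width
  classes <- base_class_table(cfg$crop_classes)
  code_of <- setNames(classes$code, classes$name)

  inner_rows <- c(ring + 1, nr - ring)
  inner_cols <- c(ring + 1, nc - ring)
  if (diff(inner_rows) + 1 < cfg$parcel_side_range[1] + 2 ||
      diff(inner_cols) + 1 < cfg$parcel_side_range[1] + 2)
    stop("grid too small to host the requested parcels inside the ",
         "perimeter ring")
  inner_area <- (diff(inner_rows) + 1) * (diff(inner_cols) + 1)

  codes <- matrix(code_of[["Grassland"]], nr, nc)
  if (ring > 0) {
    edge_dist <- pmin(row(codes) - 1, nr - row(codes),
                      col(codes) - 1, nc - col(codes))
    codes[edge_dist < ceiling(ring / 2)] <- code_of[["Natural"]]
  }

  withr::with_seed(child_seed(seed, 1), {
    blocks <- make_blocks(rows = inner_rows + c(1, -1),
                          cols = inner_cols + c(1, -1),
                          side_range = cfg$parcel_side_range,
                          gap = cfg$margin_width)
    blocks <- blocks[sample.int(length(blocks))]

    crop_codes <- code_of[cfg$crop_classes]
    painted <- 0
    bi <- 1
    paintable <- code_of[c("Grassland", "Agricultural Margin")]
    while (bi <= length(blocks) &&
           painted / inner_area < cfg$target_crop_fraction) {
      b <- blocks[[bi]]; bi <- bi + 1
      crop <- if (length(crop_codes) == 1) crop_codes else sample(crop_codes, 1)
      codes[b[1]:b[2], b[3]:b[4]] <- crop
      painted <- painted + (b[2] - b[1] + 1) * (b[4] - b[3] + 1)
      codes <- paint_margin_ring(codes, b, cfg$margin_width,
                                 code_of[["Agricultural Margin"]], paintable)
    }

    # non-crop inner land covers: rectangular patches rejection-sampled
    # onto remaining grassland (never over crops or margins, so no margin
    # is ever severed from its parcel); patch sides shrink as grassland
    # fragments so the target fractions stay reachable
    grass <- code_of[["Grassland"]]
    place_patches <- function(codes, target_cells, side_range, painter,
                              max_attempts = 4000) {
      placed <- 0
      attempt <- 0
      while (placed < target_cells && attempt < max_attempts) {
        attempt <- attempt + 1
        shrink <- max(0, (side_range[1] - 2) * (attempt / max_attempts))
        h <- max(2, sample_side(side_range) - round(shrink))
        w <- max(2, sample_side(side_range) - round(shrink))
        r0 <- sample(inner_rows[1]:(inner_rows[2] - h + 1), 1)
        c0 <- sample(inner_cols[1]:(inner_cols[2] - w + 1), 1)
        rect <- c(r0, r0 + h - 1, c0, c0 + w - 1)
        if (!all(codes[rect[1]:rect[2], rect[3]:rect[4]] == grass)) next
        codes <- painter(codes, rect)
        placed <- placed + h * w
      }
      codes
    }
    paint_flat <- function(code) function(codes, rect) {
      codes[rect[1]:rect[2], rect[3]:rect[4]] <- code
      codes
    }
    paint_urban <- function(codes, rect) {
      for (r in rect[1]:rect[2]) for (c in rect[3]:rect[4]) {
        d <- min(r - rect[1], rect[2] - r, c - rect[3], rect[4] - c)
        codes[r, c] <- if (d == 0) code_of[["Urban Greenspace"]]
          else if (d >= 3) code_of[["Urban Impervious"]]
          else code_of[["Urban"]]
      }
      codes
    }
    codes <- place_patches(codes, cfg$target_urban_fraction * inner_area,
                           cfg$urban_side_range, paint_urban)
    codes <- place_patches(codes, cfg$natural_inner_fraction * inner_area,
                           cfg$natural_side_range,
                           paint_flat(code_of[["Natural"]]))
    codes <- place_patches(codes, cfg$water_fraction * inner_area,
                           cfg$water_side_range, paint_flat(code_of[["Water"]]))
    codes <- place_patches(codes, cfg$bare_fraction * inner_area,
                           cfg$water_side_range,
                           paint_flat(code_of[["Bare Soil"]]))
  })

  grid <- land_grid(codes, cfg$cell_size, cfg$origin, classes)

  inner <- matrix(FALSE, nr, nc)
  inner[inner_rows[1]:inner_rows[2], inner_cols[1]:inner_cols[2]] <- TRUE

  line_col <- if (ring >= 2) ceiling(ring / 2) else 1
  ys <- cell_center_xy(grid, c(inner_rows[1], inner_rows[2]),
                       c(line_col, line_col))[, "y"]
  west_x <- cell_center_xy(grid, 1, line_col)[, "x"]
  east_x <- cell_center_xy(grid, 1, nc - line_col + 1)[, "x"]
  masks <- list(
    inner = inner,
    west_line = cbind(x = rep(west_x, 2), y = ys),
    east_line = cbind(x = rep(east_x, 2), y = ys)
  )
  list(grid = grid, masks = masks)
}

#' Cell-centre coordinates and cell lookup
#'
#' `cell_center_xy()` maps `(row, col)` indices to projected x/y centre
#' coordinates; `cell_at_xy()` is the inverse (points outside the grid
#' return `NA`).
#'
#' @param grid a `land_grid` (or any object with `codes`, `cell_size`,
#'   `origin`).
#' @param row,col cell indices (vectorized, 1-based, row 1 = north).
#' @return `cell_center_xy()`: two-column matrix `x`, `y`.
#' @export
cell_center_xy <- function(grid, row, col) {
  nr <- grid_dim(grid)[1]
  cbind(x = grid$origin[1] + (col - 0.5) * grid$cell_size,
        y = grid$origin[2] + (nr - row + 0.5) * grid$cell_size)
}

grid_dim <- function(grid) {
  m <- grid$codes %||% grid$values
  if (is.null(m)) stop("object carries no grid matrix")
  dim(m)
}

#' @rdname cell_center_xy
#' @param x,y projected coordinates (vectorized).
#' @return `cell_at_xy()`: two-column integer matrix `row`, `col`.
#' @export
cell_at_xy <- function(grid, x, y) {
  nr <- grid_dim(grid)[1]; nc <- grid_dim(grid)[2]
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1
  row <- nr - floor((y - grid$origin[2]) / grid$cell_size)
  bad <- row < 1 | row > nr | col < 1 | col > nc
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Inner-area land-cover fractions by role
#'
#' @param grid a `land_grid`.
#' @param mask logical matrix delimiting the area (default: whole grid).
#' @return named numeric vector of area fractions summing to 1.
#' @export
role_fractions <- function(grid, mask = NULL) {
  roles <- role_matrix(grid)
  if (!is.null(mask)) roles <- roles[mask]
  tab <- table(roles[!is.na(roles)])
  setNames(as.numeric(tab) / sum(tab), names(tab))
}
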