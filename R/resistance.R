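#' Convert a per-acre toxic load to an integer resistance value
#'
#' Resistance to movement is anchored to a landscape-genetics result for
#' bumble bees in urban landscapes: urban land (genetic-model resistance
#' 0.8, the mean of the supported 0.7-0.9 range) is eight times more
#' resistant than natural land (0.1), natural land sits at the
#' isolation-by-distance baseline of 1, and resistance is extrapolated
#' linearly in the ratio of a class's per-acre toxic load to the urban
#' load: `resistance = (class_load / urban_load) * urban_resistance`,
#' rounded half-up to a whole number and clamped to `[1, 100]` (100 = a
#' cell one hundred times harder to traverse than baseline).
#'
#' @param class_load per-acre toxic load of the land class (LD50s/acre).
#' @param urban_load per-acre toxic load of the urban class (positive).
#' @param urban_resistance the urban anchor resistance (8 for the medium
#'   scenario; 7 and 9 for low and high).
#' @param round if `FALSE`, return the raw linearly scaled value before
#'   rounding and clamping.
#' @return integer resistance in `[1, 100]` (or the raw value).
#' @export
#' @examples
#' load_to_resistance(2220400221, 1500895028, 8) # pomegranate: 12
#' load_to_resistance(2220400221, 1500895028, 8, round = FALSE) # 11.84
load_to_resistance <- function(class_load, urban_load, urban_resistance,
                               round = TRUE) {
  if (any(urban_load <= 0)) stop("urban load must be positive")
  if (any(class_load < 0)) stop("class load must be non-negative")
  if (any(urban_resistance < 1)) stop("urban resistance anchor must be >= 1")
  raw <- class_load / urban_load * urban_resistance
  if (!round) return(raw)
  as.integer(pmin(100, pmax(1, round_half_up(raw))))
}

round_half_up <- function(x) floor(x + 0.5)

#' Published land-cover resistance table
#'
#' The packaged table of low/medium/high resistance values per land-cover
#' and crop type (24 agriculture-flagged crop groups plus urban, margin,
#' and natural classes), together with each class's share of the whole
#' study area and of its agricultural interior. Used as the default source
#' of expert-assigned resistances and as a reference in tests.
#'
#' @return data frame `land_class`, `agriculture` (`"Y"` for crop groups),
#'   `pct_all_cv`, `pct_interior`, `low`, `medium`, `high`.
#' @export
table1_resistance <- function() {
  path <- system.file("extdata", "table1_resistance.csv",
                      package = "agcorridors", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname build_resistance_table
#' @export
default_expert_overrides <- function() {
  tab <- table1_resistance()
  expert <- c("Agricultural Margin", "Urban Greenspace", "Bare Soil",
              "Urban Impervious", "Water", "Natural", "Grassland")
  tab[tab$land_class %in% expert, c("land_class", "low", "medium", "high")]
}

#' Build the scenario resistance table from toxic loads
#'
#' Computes integer resistance per land class and level by linear scaling
#' of scenario toxic loads against the urban load (see
#' [load_to_resistance()]), then merges expert-opinion overrides for the
#' classes whose resistance is not pesticide-driven (agricultural margins,
#' urban greenspace, bare soil, open water, plus the natural baseline).
#' The urban class itself carries the anchor values. An `Other` row is
#' added as the rounded mean of all computed crop resistances per level.
#'
#' By default each level's crop loads are scaled against that same level's
#' urban load with per-level urban anchors (7/8/9), which keeps the urban
#' row self-consistent; `anchor_mode = "medium"` instead scales every level
#' against the medium urban load and anchor 8. Under per-level anchoring a
#' class's low/medium/high values can come out non-monotone when the urban
#' load varies much more between years than the class load does; such rows
#' are sorted into order with a warning so the table invariant
#' `low <= medium <= high` always holds.
#'
#' @param scenario_loads data frame `land_class`, `low`, `medium`, `high`
#'   of per-acre toxic loads (from [collapse_to_scenarios()]).
#' @param urban_class name of the urban anchor class (must be present).
#' @param overrides data frame `land_class`, `low`, `medium`, `high` of
#'   expert-assigned resistances; defaults to the packaged published
#'   values.
#' @param anchors named integer vector of urban anchor resistances per
#'   level.
#' @param anchor_mode `"per_level"` or `"medium"` (see Details).
#' @return data frame `land_class`, `low`, `medium`, `high`, `provenance`
#'   (`"computed"` or `"expert"`), all values integer in `[1, 100]`.
#' @export
build_resistance_table <- function(scenario_loads, urban_class = "Urban",
                                   overrides = default_expert_overrides(),
                                   anchors = c(low = 7, medium = 8, high = 9),
                                   anchor_mode = c("per_level", "medium")) {
  anchor_mode <- match.arg(anchor_mode)
  levels <- c("low", "medium", "high")
  has_urban <- urban_class %in% scenario_loads$land_class

  rows <- list()
  if (nrow(scenario_loads)) {
    if (!has_urban)
      stop("urban class '", urban_class, "' is missing from the scenario loads")
    urban <- scenario_loads[scenario_loads$land_class == urban_class, ]
    crops <- scenario_loads[scenario_loads$land_class != urban_class, ,
                            drop = FALSE]
    comp <- data.frame(land_class = crops$land_class,
                       stringsAsFactors = FALSE)
    for (lv in levels) {
      u_load <- if (anchor_mode == "per_level") urban[[lv]] else urban$medium
      u_anch <- if (anchor_mode == "per_level") anchors[[lv]] else
        anchors[["medium"]]
      comp[[lv]] <- load_to_resistance(crops[[lv]], u_load, u_anch)
    }
    mono <- comp$low <= comp$medium & comp$medium <= comp$high
    if (any(!mono)) {
      warning("sorted non-monotone computed resistances for: ",
              paste(comp$land_class[!mono], collapse = ", "))
      fixed <- t(apply(comp[!mono, levels], 1, sort))
      comp[!mono, levels] <- fixed
    }
    urban_row <- data.frame(land_class = urban_class, low = anchors[["low"]],
                            medium = anchors[["medium"]],
                            high = anchors[["high"]],
                            stringsAsFactors = FALSE)
    other_row <- data.frame(land_class = "Other",
                            low = round_half_up(mean(comp$low)),
                            medium = round_half_up(mean(comp$medium)),
                            high = round_half_up(mean(comp$high)),
                            stringsAsFactors = FALSE)
    rows$computed <- rbind(comp, urban_row, other_row)
    rows$computed$provenance <- "computed"
  }

  if (!is.null(overrides) && nrow(overrides)) {
    if (!all(c("land_class", levels) %in% names(overrides)))
      stop("overrides need columns land_class, low, medium, high")
    vals <- as.matrix(overrides[levels])
    if (any(vals < 1 | vals > 100 | vals != round(vals)))
      stop("override resistances must be integers in [1, 100]")
    ov <- overrides[c("land_class", levels)]
    ov$provenance <- "expert"
    if (!is.null(rows$computed))
      rows$computed <- rows$computed[
        !rows$computed$land_class %in% ov$land_class, , drop = FALSE]
    rows$expert <- ov
  }

  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    stop("nothing to build: no scenario loads and no overrides")
  out[levels] <- lapply(out[levels], as.integer)
  rownames(out) <- NULL
  out[order(out$land_class), ]
}

#' Apply an agricultural-margin scenario to a land-cover grid
#'
#' The three margin treatments of the factorial experiment:
#' * `"restored"` - every margin cell is recoded to the natural class,
#'   emulating restoration of field edges to pollinator habitat;
#' * `"current"` - the status quo, the grid is returned unchanged;
#' * `"none"` - fields are extended over their margins: each margin cell
#'   takes the class of its nearest crop cell (Euclidean distance between
#'   cell centres, ties to the lower row-major flat index).
#'
#' @param grid a [land_grid()] with margin and (for `"none"`) crop cells.
#' @param scenario `"restored"`, `"current"`, or `"none"`.
#' @return the recoded `land_grid`; non-margin cells are never touched.
#' @export
apply_margin_scenario <- function(grid,
                                  scenario = c("current", "restored", "none")) {
  scenario <- match.arg(scenario)
  if (scenario == "current") return(grid)
  roles <- role_matrix(grid)
  is_margin <- !is.na(roles) & roles == "margin"
  if (scenario == "restored") {
    natural_code <- grid$classes$code[grid$classes$role == "natural"][1]
    if (is.na(natural_code)) stop("grid has no natural class to restore to")
    grid$codes[is_margin] <- natural_code
  } else {
    is_crop <- !is.na(roles) & roles == "crop"
    grid$codes <- nearest_crop_codes_cpp(grid$codes, is_margin, is_crop)
  }
  grid
}

#' Rasterize a resistance table over a land-cover grid
#'
#' Per-cell lookup of the resistance value of the cell's land-cover class
#' at one level; nodata cells propagate as `NA`.
#'
#' @param grid a [land_grid()].
#' @param table resistance table from [build_resistance_table()].
#' @param level `"low"`, `"medium"`, or `"high"`.
#' @param margin_scenario optional label stored on the result.
#' @return a `resist_grid`: list with `values` (numeric matrix, `NA` =
#'   nodata), `cell_size`, `origin`, `level`, `margin_scenario`.
#' @export
rasterize_resistance <- function(grid, table,
                                 level = c("low", "medium", "high"),
                                 margin_scenario = "current") {
  level <- match.arg(level)
  lookup <- setNames(table[[level]], table$land_class)
  name_of <- setNames(grid$classes$name, grid$classes$code)
  used <- unique(grid$codes[!is.na(grid$codes)])
  missing_cls <- setdiff(name_of[as.character(used)], names(lookup))
  if (length(missing_cls))
    stop("no resistance entry at level '", level, "' for class(es): ",
         paste(missing_cls, collapse = ", "))
  vals <- lookup[name_of[as.character(grid$codes)]]
  values <- matrix(as.numeric(vals), nrow(grid$codes))
  values[is.na(grid$codes)] <- NA_real_
  structure(list(values = values, cell_size = grid$cell_size,
                 origin = grid$origin, level = level,
                 margin_scenario = margin_scenario),
            class = "resist_grid")
}

#' @export
print.resist_grid <- function(x, ...) {
  cat(sprintf("<resist_grid> %d x %d, level %s, margins %s, range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$level, x$margin_scenario,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}
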