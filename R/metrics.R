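#' Construct a path set by hand
#'
#' Wraps a list of [trace_path()] results (or hand-built paths with a
#' `cells` matrix) together with the grid geometry the metrics need.
#'
#' @param paths list of `lcp_path` objects.
#' @param dim grid dimensions `c(nrow, ncol)`.
#' @param cell_size cell edge in metres.
#' @param origin lower-left corner coordinates.
#' @param margin_scenario,level scenario labels.
#' @return an `lcp_set`.
#' @export
lcp_set <- function(paths, dim, cell_size = 30, origin = c(0, 0),
                    margin_scenario = "current", level = "medium") {
  structure(list(paths = paths, cell_size = cell_size, origin = origin,
                 dim = dim, margin_scenario = margin_scenario,
                 level = level, n_pairs = length(paths), n_dropped = 0L),
            class = "lcp_set")
}

# One row per cell-to-cell move over all paths in a set. Moves are
# canonicalized to an undirected key (lower flat index first, row-major
# 0-based) so overlap is insensitive to path direction; `inner` marks moves
# whose midpoint lies inside the inner area, operationalized as both
# endpoint cells inner (a boundary-straddling move, whose midpoint sits
# exactly on the inner boundary, is counted as outside).
set_moves <- function(set, inner_mask = NULL) {
  nc <- set$dim[2]
  per_path <- lapply(seq_along(set$paths), function(pi) {
    cells <- set$paths[[pi]]$cells
    n <- nrow(cells)
    if (n < 2) return(NULL)
    from <- cells[-n, , drop = FALSE]
    to <- cells[-1, , drop = FALSE]
    f1 <- (from[, 1] - 1) * nc + (from[, 2] - 1)
    f2 <- (to[, 1] - 1) * nc + (to[, 2] - 1)
    diag <- (abs(from[, 1] - to[, 1]) + abs(from[, 2] - to[, 2])) == 2
    inner <- if (is.null(inner_mask)) rep(TRUE, n - 1) else
      inner_mask[from] & inner_mask[to]
    data.frame(a = pmin(f1, f2), b = pmax(f1, f2),
               to_row = to[, 1], to_col = to[, 2],
               len = set$cell_size * ifelse(diag, sqrt(2), 1),
               inner = inner, path = pi,
               iteration = set$paths[[pi]]$iteration %||% 1L)
  })
  out <- do.call(rbind, per_path)
  if (is.null(out))
    out <- data.frame(a = integer(), b = integer(), to_row = integer(),
                      to_col = integer(), len = numeric(),
                      inner = logical(), path = integer(),
                      iteration = integer())
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_aligned <- function(set, mask) {
  if (!is.matrix(mask) || !all(dim(mask) == set$dim))
    stop("inner mask (", paste(dim(mask), collapse = " x "),
         ") is not aligned to the path grid (",
         paste(set$dim, collapse = " x "), ")")
  invisible(TRUE)
}

#' Total least-cost path length
#'
#' Sum of the Euclidean lengths of all paths in the set (duplicated or
#' overlapping paths count every time), inside and outside the inner area;
#' a measure of the directness of routes.
#'
#' @param set an `lcp_set`.
#' @return kilometres (0 for an empty set).
#' @export
total_path_length <- function(set) {
  sum(vapply(set$paths, function(p) p$length_m, 1)) / 1000
}

#' Unique (non-overlapping) path length in the inner area
#'
#' Length of the union of path segments inside the inner study area:
#' paths are decomposed into cell-to-cell moves, moves are canonicalized so
#' direction does not matter, moves whose midpoint lies outside the inner
#' area are discarded, and each distinct move contributes its length once.
#' A measure of the redundancy versus spread of the corridor network.
#'
#' @param set an `lcp_set`.
#' @param inner_mask logical matrix delimiting the inner study area.
#' @return kilometres.
#' @export
unique_path_length <- function(set, inner_mask) {
  check_aligned(set, inner_mask)
  mv <- set_moves(set, inner_mask)
  mv <- mv[mv$inner, , drop = FALSE]
  mv <- mv[!duplicated(mv[c("a", "b")]), , drop = FALSE]
  sum(mv$len) / 1000
}

#' Mean distance from inner-area cells to the nearest path
#'
#' Rasterizes all path cells and applies an exact Euclidean distance
#' transform over the full grid; the mean of the distances over all
#' inner-area cells indicates how hard a least-cost route is to access.
#'
#' @param set an `lcp_set`.
#' @param inner_mask logical matrix delimiting the inner study area.
#' @return kilometres, or `NA` (with a warning) when the set is empty.
#' @export
mean_distance_to_path <- function(set, inner_mask) {
  check_aligned(set, inner_mask)
  if (length(set$paths) == 0) {
    warning("no paths: mean distance to path is undefined")
    return(NA_real_)
  }
  occupied <- matrix(1, set$dim[1], set$dim[2])
  for (p in set$paths) occupied[p$cells] <- 0
  d <- EBImage::distmap(occupied, metric = "euclidean")
  mean(d[inner_mask]) * set$cell_size / 1000
}

#' Mean number of convergent paths per inner path cell
#'
#' For every inner-area cell traversed by at least one path, the number of
#' distinct paths through it; returns the mean over those cells. 1 means
#' no two paths share a cell; large values indicate funnelling of many
#' routes through few cells.
#'
#' @param set an `lcp_set`.
#' @param inner_mask logical matrix delimiting the inner study area.
#' @return mean count, or `NA` (with a warning) when no path cell is inner.
#' @export
mean_convergent_paths <- function(set, inner_mask) {
  check_aligned(set, inner_mask)
  tally <- matrix(0L, set$dim[1], set$dim[2])
  for (p in set$paths) {
    cells <- unique_cells(p$cells)
    tally[cells] <- tally[cells] + 1L
  }
  counts <- tally[inner_mask & tally > 0L]
  if (length(counts) == 0) {
    warning("no inner path cells: convergence is undefined")
    return(NA_real_)
  }
  mean(counts)
}

unique_cells <- function(cells) {
  cells[!duplicated(cells[, 1] * 1e6 + cells[, 2]), , drop = FALSE]
}

#' Path commonality across the three resistance levels
#'
#' Classifies every distinct path move in the union of the three levels'
#' path sets by how many levels (3, 2, or 1) contain it, and reports the
#' length-weighted fraction of the union in each category. High three-level
#' commonality means corridor placement is robust to resistance
#' uncertainty.
#'
#' @param sets_by_level named list with elements `low`, `medium`, `high`,
#'   each an `lcp_set` on the same grid.
#' @param inner_mask optional logical matrix; when supplied only moves
#'   inside the inner area are classified (default: full extent).
#' @return named numeric `c(all_three, two, one)` summing to 1.
#' @export
commonality_across_levels <- function(sets_by_level, inner_mask = NULL) {
  if (!all(c("low", "medium", "high") %in% names(sets_by_level)))
    stop("commonality needs path sets for all of low, medium, high")
  level_moves <- lapply(sets_by_level[c("low", "medium", "high")],
                        function(set) {
    mv <- set_moves(set, inner_mask)
    if (!is.null(inner_mask)) mv <- mv[mv$inner, , drop = FALSE]
    mv <- mv[!duplicated(mv[c("a", "b")]), , drop = FALSE]
    mv$key <- paste(mv$a, mv$b)
    mv
  })
  all_mv <- do.call(rbind, level_moves)
  if (nrow(all_mv) == 0)
    stop("no moves to classify")
  n_levels <- table(all_mv$key)
  uni <- all_mv[!duplicated(all_mv$key), , drop = FALSE]
  counts <- as.integer(n_levels[uni$key])
  total <- sum(uni$len)
  c(all_three = sum(uni$len[counts == 3]) / total,
    two = sum(uni$len[counts == 2]) / total,
    one = sum(uni$len[counts == 1]) / total)
}

#' Land-cover composition of least-cost paths
#'
#' Attributes the length of every move to the land-cover group of the cell
#' it enters (the first cell of a path contributes nothing) and normalizes
#' by total length. The default grouping collapses all crop classes into
#' `crop` and the three urban classes into `urban`; other roles keep their
#' own name.
#'
#' @param set an `lcp_set`.
#' @param grid the [land_grid()] the paths were traced on.
#' @param grouping named character vector mapping class roles to groups.
#' @return named numeric vector of length fractions summing to 1.
#' @export
landcover_composition <- function(set, grid, grouping = default_grouping()) {
  mv <- set_moves(set)
  if (nrow(mv) == 0) return(setNames(numeric(0), character(0)))
  roles <- role_matrix(grid)
  role <- roles[cbind(mv$to_row, mv$to_col)]
  if (any(is.na(role)))
    stop("path enters nodata or unmapped cells")
  grp <- grouping[role]
  if (any(is.na(grp)))
    stop("no composition group for role(s): ",
         paste(unique(role[is.na(grp)]), collapse = ", "))
  agg <- tapply(mv$len, grp, sum)
  setNames(as.numeric(agg) / sum(mv$len), names(agg))
}

#' @rdname landcover_composition
#' @export
default_grouping <- function() {
  c(crop = "crop", margin = "margin", natural = "natural",
    grassland = "grassland", urban = "urban", urban_greenspace = "urban",
    urban_impervious = "urban", bare = "bare", water = "water",
    other = "other")
}

#' Per-iteration connectivity metrics of a scenario run
#'
#' Computes the four headline connectivity statistics - total path length,
#' unique inner path length, mean distance to the nearest path, and mean
#' convergent paths - separately for each iteration of a scenario run.
#' Cross-iteration aggregation (mean and standard deviation) is done by
#' [summarise_metrics()].
#'
#' @param set an `lcp_set` from [run_scenario()].
#' @param inner_mask logical matrix delimiting the inner study area.
#' @return tidy data frame, one row per iteration, with the scenario
#'   labels, `n_paths`, and the four metrics.
#' @export
connectivity_metrics <- function(set, inner_mask) {
  iters <- vapply(set$paths, function(p) p$iteration %||% 1L, 1L)
  iter_ids <- if (length(iters)) sort(unique(iters)) else 1L
  rows <- lapply(iter_ids, function(it) {
    sub <- set
    sub$paths <- set$paths[iters == it]
    data.frame(
      margin_scenario = set$margin_scenario, level = set$level,
      iteration = it, n_paths = length(sub$paths),
      total_path_length_km = total_path_length(sub),
      unique_path_length_inner_km = unique_path_length(sub, inner_mask),
      mean_distance_to_path_km = mean_distance_to_path(sub, inner_mask),
      mean_convergent_paths = mean_convergent_paths(sub, inner_mask),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname connectivity_metrics
#' @param metrics per-iteration metrics data frame (possibly covering
#'   several scenarios).
#' @return `summarise_metrics()`: one row per scenario and statistic
#'   (`mean`, `sd`) across iterations.
#' @export
summarise_metrics <- function(metrics) {
  vars <- c("n_paths", "total_path_length_km",
            "unique_path_length_inner_km", "mean_distance_to_path_km",
            "mean_convergent_paths")
  out <- list()
  for (key in split(metrics,
                    list(metrics$margin_scenario, metrics$level),
                    drop = TRUE)) {
    for (stat in c("mean", "sd")) {
      f <- if (stat == "mean") function(v) mean(v, na.rm = TRUE) else
        function(v) sd(v, na.rm = TRUE)
      row <- data.frame(margin_scenario = key$margin_scenario[1],
                        level = key$level[1], stat = stat,
                        stringsAsFactors = FALSE)
      for (v in vars) row[[v]] <- f(key[[v]])
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
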