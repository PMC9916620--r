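#' Cost-distance from a set of source cells
#'
#' Accumulated least-cost distance over a resistance surface via Dijkstra's
#' algorithm on the 8-connected cell graph, the standard GIS Cost Distance
#' operation: the cost of a move between neighbouring cells is the mean of
#' their two resistances times the move length (1 cell orthogonally,
#' sqrt(2) diagonally), so accumulated values are in cost-distance units
#' (cells traversed times cost). Alongside the accumulated grid a backlink
#' grid records, for every reached cell, the direction to its predecessor
#' on the optimal route (codes 1-8 clockwise from north; 0 = source or
#' unreached), which [trace_path()] follows. Nodata cells (`NA`) are
#' impassable; unreached cells hold `Inf`. Equal-cost ties are broken
#' deterministically by the lower row-major flat cell index.
#'
#' @param resistance a `resist_grid` from [rasterize_resistance()], or a
#'   numeric matrix of resistances (`NA` = nodata).
#' @param sources two-column matrix of source cells (`row`, `col`).
#' @return a `cost_surface`: list with `accumulated`, `backlink`,
#'   `sources`, `cell_size`, `origin`.
#' @export
#' @examples
#' surf <- cost_distance(matrix(1, 5, 5), cbind(3, 1))
#' surf$accumulated[3, 5] # 4 cells at resistance 1
cost_distance <- function(resistance, sources) {
  values <- if (inherits(resistance, "resist_grid")) resistance$values
    else resistance
  cell_size <- if (inherits(resistance, "resist_grid"))
    resistance$cell_size else 1
  origin <- if (inherits(resistance, "resist_grid")) resistance$origin
    else c(0, 0)
  sources <- matrix(as.integer(sources), ncol = 2)
  if (nrow(sources) == 0) stop("at least one source cell is required")
  on_nodata <- is.na(values[sources])
  if (all(on_nodata)) stop("all source cells lie on nodata")
  if (any(on_nodata))
    warning(sum(on_nodata), " source cell(s) on nodata were dropped")
  res <- cost_distance_cpp(values, sources[, 1], sources[, 2])
  structure(list(accumulated = res$accumulated, backlink = res$backlink,
                 sources = sources[!on_nodata, , drop = FALSE],
                 cell_size = cell_size, origin = origin),
            class = "cost_surface")
}

# backlink direction codes -> (row, col) offsets; must mirror the C++ table
.dir_row <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
.dir_col <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

#' Trace a least-cost path from a destination cell
#'
#' Follows the backlink grid of a [cost_distance()] surface from the
#' destination back to the nearest source and reverses the walk, yielding
#' the source-to-destination least-cost path as a sequence of cells. The
#' path's total cost equals the accumulated cost at the destination, and
#' its Euclidean length is the sum of per-move lengths (`cell_size` per
#' orthogonal move, `cell_size * sqrt(2)` per diagonal move).
#'
#' @param surface a `cost_surface`.
#' @param destination length-2 vector `(row, col)`.
#' @param ... metadata stored on the path (e.g. `source_id`, `dest_id`,
#'   `iteration`, `margin_scenario`, `level`).
#' @return an `lcp_path`: list with `cells` (n x 2 matrix, source first),
#'   `total_cost`, `length_m`, and any metadata; or an error condition of
#'   class `agcorridors_unreachable` when the destination was not reached.
#' @export
trace_path <- function(surface, destination, ...) {
  r <- destination[1]; c <- destination[2]
  acc <- surface$accumulated[r, c]
  if (!is.finite(acc))
    stop(structure(class = c("agcorridors_unreachable", "error", "condition"),
                   list(message = sprintf(
                     "destination cell (%d, %d) is unreachable", r, c),
                     call = sys.call())))
  nr <- nrow(surface$accumulated)
  cells <- matrix(NA_integer_, nr * ncol(surface$accumulated), 2)
  n <- 0L
  repeat {
    n <- n + 1L
    cells[n, ] <- c(r, c)
    dir <- surface$backlink[r, c]
    if (dir == 0L) break
    r <- r + .dir_row[dir]
    c <- c + .dir_col[dir]
  }
  cells <- cells[n:1, , drop = FALSE]
  moves_diag <- rowSums(abs(cells[-1, , drop = FALSE] -
                            cells[-n, , drop = FALSE])) == 2
  length_m <- surface$cell_size *
    (sum(!moves_diag) + sqrt(2) * sum(moves_diag))
  structure(c(list(cells = cells, total_cost = acc, length_m = length_m),
              list(...)),
            class = "lcp_path")
}

#' @export
print.lcp_path <- function(x, ...) {
  cat(sprintf("<lcp_path> %d cells, cost %.3f, length %.3f km\n",
              nrow(x$cells), x$total_cost, x$length_m / 1000))
  invisible(x)
}
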