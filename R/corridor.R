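#' Corridor-experiment run configuration
#'
#' Parameters controlling endpoint placement and the iteration scheme. The
#' defaults are the valley-scale settings of the study design: endpoints
#' every 5 km along the two perimeter lines, west-east pairs within a
#' 125 km Euclidean buffer, and 20 iterations in which endpoints are
#' jittered uniformly within 5 km of their original position. Desk-scale
#' experiments on the default synthetic landscape pass smaller spacing and
#' jitter (600 m) and fewer iterations.
#'
#' @param point_spacing_m arc-length spacing of perimeter points (m).
#' @param max_pair_distance_m maximum Euclidean west-east pairing distance.
#' @param jitter_radius_m radius of the uniform jitter disc (0 = none).
#' @param n_iterations number of iterations (>= 1). Iteration 1 uses the
#'   original unjittered points unless `jitter_first = TRUE`, so the
#'   canonical endpoint configuration is always represented.
#' @param jitter_first jitter iteration 1 as well.
#' @param max_jitter_tries rejection-sampling budget per jittered point.
#' @param seed master seed for the run.
#' @return a list of class `run_config`.
#' @export
run_config <- function(point_spacing_m = 5000, max_pair_distance_m = 125000,
                       jitter_radius_m = 5000, n_iterations = 20,
                       jitter_first = FALSE, max_jitter_tries = 100,
                       seed = 1) {
  stopifnot(point_spacing_m > 0, max_pair_distance_m > 0,
            jitter_radius_m >= 0, n_iterations >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Place equally spaced points along a polyline
#'
#' Points are placed by arc length at positions `0, s, 2s, ...` from the
#' first vertex (the start vertex is always included), giving
#' `floor(length / s) + 1` points; positions falling inside a segment are
#' linearly interpolated.
#'
#' @param line two-column matrix of polyline vertices (`x`, `y`, metres).
#' @param spacing_m spacing `s` in metres (positive).
#' @return two-column matrix of point coordinates.
#' @export
#' @examples
#' perimeter_points(cbind(c(0, 10000), c(0, 0)), 5000) # 3 points
perimeter_points <- function(line, spacing_m) {
  stopifnot(spacing_m > 0)
  line <- matrix(as.numeric(line), ncol = 2)
  seg <- sqrt(rowSums((line[-1, , drop = FALSE] -
                       line[-nrow(line), , drop = FALSE])^2))
  total <- sum(seg)
  if (nrow(line) < 2 || total <= 0)
    stop("perimeter line has zero length")
  cum <- c(0, cumsum(seg))
  pos <- seq(0, total, by = spacing_m)
  t(vapply(pos, function(p) {
    i <- max(which(cum <= p + 1e-9))
    if (i >= nrow(line)) return(line[nrow(line), ])
    f <- (p - cum[i]) / seg[i]
    line[i, ] + f * (line[i + 1, ] - line[i, ])
  }, numeric(2)))
}

#' Jitter points uniformly within a disc
#'
#' Each point is displaced to a uniform random position on the disc of the
#' given radius around it (expected displacement `2r/3`), re-drawn until it
#' lands on a valid cell of the grid; after the retry budget is exhausted
#' the original point is kept with a warning. Draws for point `i` use
#' `child_seed(seed, i)`, so individual points are reproducible
#' independently of the rest of the list.
#'
#' @param points two-column coordinate matrix.
#' @param radius_m jitter radius in metres (0 returns the input unchanged).
#' @param seed integer seed.
#' @param grid optional `land_grid` (or `resist_grid`) used to validate
#'   candidate positions: inside the extent and not nodata.
#' @param max_tries rejection-sampling budget per point.
#' @return two-column coordinate matrix of jittered points.
#' @export
jitter_points <- function(points, radius_m, seed, grid = NULL,
                          max_tries = 100) {
  stopifnot(radius_m >= 0)
  points <- matrix(as.numeric(points), ncol = 2)
  if (radius_m == 0) return(points)
  values <- if (inherits(grid, "resist_grid")) grid$values
    else if (inherits(grid, "land_grid")) grid$codes else NULL
  valid <- function(p) {
    if (is.null(grid)) return(TRUE)
    rc <- cell_at_xy(grid, p[1], p[2])
    !is.na(rc[1]) && !is.na(values[rc[1], rc[2]])
  }
  out <- points
  for (i in seq_len(nrow(points))) {
    out[i, ] <- withr::with_seed(child_seed(seed, i), {
      res <- NULL
      for (k in seq_len(max_tries)) {
        r <- radius_m * sqrt(runif(1))
        a <- runif(1) * 2 * pi
        cand <- points[i, ] + r * c(cos(a), sin(a))
        if (valid(cand)) { res <- cand; break }
      }
      if (is.null(res)) {
        warning("no valid jitter position for point ", i,
                " after ", max_tries, " tries; keeping the original")
        res <- points[i, ]
      }
      res
    })
  }
  out
}

#' Pair west and east perimeter points within a distance buffer
#'
#' All (west, east) combinations whose Euclidean distance does not exceed
#' the threshold, in stable (west index, east index) order.
#'
#' @param west,east two-column coordinate matrices.
#' @param max_distance_m pairing threshold in metres.
#' @return data frame `west_id`, `east_id`, `distance_m`.
#' @export
pair_points <- function(west, east, max_distance_m) {
  west <- matrix(as.numeric(west), ncol = 2)
  east <- matrix(as.numeric(east), ncol = 2)
  stopifnot(nrow(west) > 0, nrow(east) > 0)
  grid <- expand.grid(east_id = seq_len(nrow(east)),
                      west_id = seq_len(nrow(west)))
  d <- sqrt((west[grid$west_id, 1] - east[grid$east_id, 1])^2 +
            (west[grid$west_id, 2] - east[grid$east_id, 2])^2)
  out <- data.frame(west_id = grid$west_id, east_id = grid$east_id,
                    distance_m = d)
  out <- out[d <= max_distance_m, , drop = FALSE]
  out <- out[order(out$west_id, out$east_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the corridor experiment for one scenario
#'
#' Executes the full least-cost corridor procedure for one margin-scenario
#' x resistance-level combination: apply the margin treatment to the land
#' cover, rasterize the resistance table, place perimeter points, then for
#' each iteration jitter the endpoints, pair west to east within the
#' distance buffer, run one cost-distance computation per unique source
#' point and trace the least-cost path to each of its paired destinations.
#' Pairs whose destination is unreachable are dropped and counted.
#'
#' Jitter seeds depend only on (master seed, iteration, side), not on the
#' scenario, so all nine scenarios of the factorial see identical endpoint
#' realizations - a paired design that isolates the landscape treatment
#' from endpoint noise.
#'
#' @param grid a [land_grid()].
#' @param masks study masks from [generate_landscape()].
#' @param rtable resistance table from [build_resistance_table()].
#' @param margin_scenario `"restored"`, `"current"`, or `"none"`.
#' @param level `"low"`, `"medium"`, or `"high"`.
#' @param config a [run_config()].
#' @return an `lcp_set`: list with `paths` (list of `lcp_path`),
#'   `cell_size`, `origin`, `dim`, scenario labels, and counts
#'   `n_pairs`, `n_dropped`.
#' @export
run_scenario <- function(grid, masks, rtable,
                         margin_scenario = c("current", "restored", "none"),
                         level = c("medium", "low", "high"),
                         config = run_config()) {
  margin_scenario <- match.arg(margin_scenario)
  level <- match.arg(level)
  g <- apply_margin_scenario(grid, margin_scenario)
  resist <- rasterize_resistance(g, rtable, level, margin_scenario)

  west0 <- perimeter_points(masks$west_line, config$point_spacing_m)
  east0 <- perimeter_points(masks$east_line, config$point_spacing_m)

  paths <- list()
  n_pairs <- 0L
  n_dropped <- 0L
  for (iter in seq_len(config$n_iterations)) {
    if (iter == 1 && !config$jitter_first) {
      west <- west0; east <- east0
    } else {
      west <- jitter_points(west0, config$jitter_radius_m,
                            child_seed(config$seed, 10L, iter, 1L),
                            grid = resist, max_tries = config$max_jitter_tries)
      east <- jitter_points(east0, config$jitter_radius_m,
                            child_seed(config$seed, 10L, iter, 2L),
                            grid = resist, max_tries = config$max_jitter_tries)
    }
    pairs <- pair_points(west, east, config$max_pair_distance_m)
    n_pairs <- n_pairs + nrow(pairs)
    wcells <- cell_at_xy(resist, west[, 1], west[, 2])
    ecells <- cell_at_xy(resist, east[, 1], east[, 2])
    for (w in unique(pairs$west_id)) {
      surf <- cost_distance(resist, wcells[w, , drop = FALSE])
      for (e in pairs$east_id[pairs$west_id == w]) {
        p <- tryCatch(
          trace_path(surf, ecells[e, ], source_id = w, dest_id = e,
                     iteration = iter, margin_scenario = margin_scenario,
                     level = level),
          agcorridors_unreachable = function(cnd) NULL)
        if (is.null(p)) n_dropped <- n_dropped + 1L else
          paths[[length(paths) + 1L]] <- p
      }
    }
  }
  if (n_dropped > 0)
    message(n_dropped, " unreachable pair(s) dropped in ",
            margin_scenario, "/", level)
  structure(list(paths = paths, cell_size = grid$cell_size,
                 origin = grid$origin, dim = dim(grid$codes),
                 margin_scenario = margin_scenario, level = level,
                 n_pairs = n_pairs, n_dropped = n_dropped),
            class = "lcp_set")
}

#' @export
print.lcp_set <- function(x, ...) {
  cat(sprintf("<lcp_set> %s margins / %s resistance: %d paths (%d pairs, %d dropped)\n",
              x$margin_scenario, x$level, length(x$paths), x$n_pairs,
              x$n_dropped))
  invisible(x)
}

#' Run the full 3 x 3 margin-by-resistance factorial
#'
#' Runs [run_scenario()] for every combination of margin treatment and
#' resistance level and summarises each run with the connectivity metrics
#' (see [connectivity_metrics()]), computed per iteration and then
#' averaged.
#'
#' @inheritParams run_scenario
#' @param margins,levels the factor levels to cross.
#' @return list with `paths` (named `lcp_set` list, names
#'   `<margin>_<level>`), `metrics` (per-iteration tidy data frame),
#'   `summary` (mean/sd per scenario), and `composition` (tidy land-cover
#'   composition of paths per scenario).
#' @export
run_experiment <- function(grid, masks, rtable, config = run_config(),
                           margins = c("restored", "current", "none"),
                           levels = c("low", "medium", "high")) {
  sets <- list()
  metrics <- list()
  comp <- list()
  for (m in margins) for (lv in levels) {
    key <- paste(m, lv, sep = "_")
    set <- run_scenario(grid, masks, rtable, m, lv, config)
    sets[[key]] <- set
    metrics[[key]] <- connectivity_metrics(set, masks$inner)
    cp <- landcover_composition(set, grid)
    comp[[key]] <- data.frame(margin_scenario = m, level = lv,
                              group = names(cp), fraction = as.numeric(cp),
                              stringsAsFactors = FALSE)
  }
  metrics_df <- do.call(rbind, c(metrics, make.row.names = FALSE))
  list(paths = sets, metrics = metrics_df,
       summary = summarise_metrics(metrics_df),
       composition = do.call(rbind, c(comp, make.row.names = FALSE)))
}
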