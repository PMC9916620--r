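# Shared fixtures built in code: a small landscape that exercises every
# land-cover role, toy pesticide tables with hand-checkable numbers, and an
# independent brute-force cost-distance oracle.

small_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_landscape(
        landscape_config(nrow = 100, ncol = 140, ring_width = 8,
                         parcel_side_range = c(12, 18)), seed = 1)
    cache
  }
})

# One-parcel configuration: a single 10 x 10 parcel on a 20 x 20 grid with
# no perimeter ring and no other land covers.
one_parcel_config <- function() {
  landscape_config(nrow = 20, ncol = 20, ring_width = 0,
                   parcel_side_range = c(10, 10),
                   target_crop_fraction = 100 / 400,
                   target_urban_fraction = 0, natural_inner_fraction = 0,
                   water_fraction = 0, bare_fraction = 0)
}

# Hand-set pesticide tables: three chemicals on two classes over 3 years.
toy_tables <- function() {
  list(
    use_records = data.frame(
      chemical = rep(c("A", "B", "C"), each = 3),
      land_class = "Almonds",
      year = rep(2014:2016, 3),
      pounds = c(1, 2, 3, 10, 10, 10, 0.5, 0.25, 1),
      stringsAsFactors = FALSE),
    ld50 = data.frame(chemical = c("A", "B", "C"),
                      ld50_ug_per_bee = c(0.01, 0.5, 2),
                      stringsAsFactors = FALSE),
    acreage = data.frame(land_class = c("Almonds", "Urban"),
                         acres = c(1000, 500), stringsAsFactors = FALSE)
  )
}

# Independent cost-distance oracle: enumerate every directed edge of the
# 8-connected cell graph explicitly and ask igraph for shortest paths.
# Shares no code with the package's Dijkstra engine.
oracle_cost_distance <- function(resistance, src) {
  nr <- nrow(resistance); nc <- ncol(resistance)
  id <- function(i, j) (i - 1) * nc + j
  edges <- integer(0); wts <- numeric(0)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(resistance[i, j]) || !is.finite(resistance[i, j])) next
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i2 <- i + di; j2 <- j + dj
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
      if (is.na(resistance[i2, j2]) || !is.finite(resistance[i2, j2])) next
      edges <- c(edges, id(i, j), id(i2, j2))
      wts <- c(wts, (resistance[i, j] + resistance[i2, j2]) / 2 *
                 if (di != 0 && dj != 0) sqrt(2) else 1)
    }
  }
  g <- igraph::make_graph(edges, n = nr * nc, directed = TRUE)
  d <- igraph::distances(g, v = id(src[1], src[2]), weights = wts,
                         mode = "out")
  matrix(d, nr, nc, byrow = TRUE)
}

# Recompute a traced path's cost move by move from the resistance grid.
path_cost_by_hand <- function(cells, resistance) {
  n <- nrow(cells)
  if (n < 2) return(0)
  total <- 0
  for (k in 2:n) {
    a <- cells[k - 1, ]; b <- cells[k, ]
    len <- if (all(abs(a - b) == 1)) sqrt(2) else 1
    total <- total + (resistance[a[1], a[2]] + resistance[b[1], b[2]]) / 2 * len
  }
  total
}

# Build an lcp_path by hand from a cell matrix (for metric tests).
hand_path <- function(cells, cell_size = 30, iteration = 1L, ...) {
  cells <- matrix(as.integer(cells), ncol = 2)
  n <- nrow(cells)
  diag <- if (n > 1)
    rowSums(abs(cells[-1, , drop = FALSE] - cells[-n, , drop = FALSE])) == 2
  else logical(0)
  structure(list(cells = cells, total_cost = NA_real_,
                 length_m = cell_size * (sum(!diag) + sqrt(2) * sum(diag)),
                 iteration = iteration, ...),
            class = "lcp_path")
}
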