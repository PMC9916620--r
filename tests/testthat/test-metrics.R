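test_that("total path length sums every path, duplicates included", {
  p <- hand_path(cbind(5, 1:11))            # 10 orthogonal moves, 30 m
  set <- lcp_set(list(p), dim = c(10, 20))
  expect_equal(total_path_length(set), 0.3)
  expect_equal(total_path_length(lcp_set(list(p, p), dim = c(10, 20))), 0.6)
  expect_equal(total_path_length(lcp_set(list(), dim = c(10, 20))), 0)
})

test_that("unique path length dedups shared moves inside the inner area", {
  inner <- matrix(TRUE, 10, 20)
  a <- hand_path(cbind(5, 1:11))
  # shares the 4 moves between columns 4..8 in row 5, then diverges
  b <- hand_path(rbind(cbind(7, 1:3), cbind(6, 3), cbind(5, 4:8),
                       cbind(6, 9), cbind(7, 9:10)))
  expect_equal(nrow(b$cells), 12)  # 11 moves: 9 orthogonal, 2 diagonal
  set <- lcp_set(list(a, b), dim = c(10, 20))
  shared <- 4  # moves 4-5, 5-6, 6-7, 7-8 in row 5
  expect_equal(unique_path_length(lcp_set(list(a, a), dim = c(10, 20)), inner),
               unique_path_length(lcp_set(list(a), dim = c(10, 20)), inner))
  got <- unique_path_length(set, inner)
  orth <- 10 + 9 - shared
  expect_equal(got, (orth * 30 + 2 * 30 * sqrt(2)) / 1000)

  # a path entirely outside the inner area contributes nothing
  outer_only <- matrix(FALSE, 10, 20)
  expect_equal(unique_path_length(set, outer_only), 0)
})

test_that("unique length is invariant to duplication, order and reversal", {
  inner <- matrix(TRUE, 10, 20)
  a <- hand_path(cbind(5, 1:11))
  b <- hand_path(cbind(3, 2:9))
  rev_b <- hand_path(b$cells[nrow(b$cells):1, ])
  u1 <- unique_path_length(lcp_set(list(a, b), dim = c(10, 20)), inner)
  u2 <- unique_path_length(lcp_set(list(b, a), dim = c(10, 20)), inner)
  u3 <- unique_path_length(lcp_set(list(a, rev_b, a, b), dim = c(10, 20)),
                           inner)
  expect_equal(u1, u2)
  expect_equal(u1, u3)
})

test_that("mean distance to path matches the closed-form column case", {
  # single full-height path in column 1; inner strip = 5 columns of row 3
  dims <- c(5, 7)
  p <- hand_path(cbind(1:5, 1))
  inner <- matrix(FALSE, dims[1], dims[2])
  inner[3, 1:5] <- TRUE
  set <- lcp_set(list(p), dim = dims, cell_size = 30)
  expect_equal(mean_distance_to_path(set, inner),
               mean(0:4) * 30 / 1000)
  # doubling the cell size doubles the result exactly
  set60 <- lcp_set(list(p), dim = dims, cell_size = 60)
  expect_equal(mean_distance_to_path(set60, inner),
               2 * mean_distance_to_path(set, inner))
  # paths covering every inner cell give zero
  cover <- hand_path(cbind(3, 1:5))
  expect_equal(mean_distance_to_path(lcp_set(list(cover), dim = dims), inner),
               0)
  # empty set: undefined, reported missing
  expect_warning(
    na <- mean_distance_to_path(lcp_set(list(), dim = dims), inner),
    "undefined")
  expect_true(is.na(na))
})

test_that("convergence counts distinct paths per occupied inner cell", {
  inner <- matrix(TRUE, 9, 9)
  one <- hand_path(cbind(5, 1:9))
  expect_equal(mean_convergent_paths(lcp_set(list(one), dim = c(9, 9)),
                                     inner), 1)
  # two 9-cell paths crossing at exactly one cell: (16*1 + 1*2) / 17
  horiz <- hand_path(cbind(5, 1:9))
  vert <- hand_path(cbind(1:9, 5))
  expect_equal(
    mean_convergent_paths(lcp_set(list(horiz, vert), dim = c(9, 9)), inner),
    18 / 17)
  # k identical paths converge k-fold
  k <- 4
  expect_equal(
    mean_convergent_paths(lcp_set(rep(list(one), k), dim = c(9, 9)), inner),
    k)
  expect_warning(
    na <- mean_convergent_paths(lcp_set(list(), dim = c(9, 9)), inner),
    "undefined")
  expect_true(is.na(na))
})

test_that("commonality classifies moves by how many levels share them", {
  dims <- c(10, 20)
  a <- hand_path(cbind(5, 1:11))
  b <- hand_path(cbind(3, 1:11))
  c3 <- hand_path(cbind(7, 1:11))
  same <- list(low = lcp_set(list(a), dims), medium = lcp_set(list(a), dims),
               high = lcp_set(list(a), dims))
  expect_equal(commonality_across_levels(same),
               c(all_three = 1, two = 0, one = 0))
  disjoint <- list(low = lcp_set(list(a), dims),
                   medium = lcp_set(list(b), dims),
                   high = lcp_set(list(c3), dims))
  expect_equal(commonality_across_levels(disjoint),
               c(all_three = 0, two = 0, one = 1))
  # low = a+b, medium = a, high = a+c: a in three, b and c in one each;
  # all 30 moves equal length so fractions are 10/30, 0, 20/30
  mixed <- list(low = lcp_set(list(a, b), dims),
                medium = lcp_set(list(a), dims),
                high = lcp_set(list(a, c3), dims))
  expect_equal(commonality_across_levels(mixed),
               c(all_three = 1 / 3, two = 0, one = 2 / 3))
  expect_error(commonality_across_levels(list(low = lcp_set(list(a), dims))),
               "low, medium, high")
})

test_that("composition attributes each move to the cell it enters", {
  classes <- base_class_table("OnlyCrop")
  codes <- matrix(1L, 10, 20)  # natural everywhere
  g <- land_grid(codes, 30, classes = classes)
  p <- hand_path(cbind(5, 1:11))
  expect_equal(landcover_composition(lcp_set(list(p), dim = c(10, 20)), g),
               c(natural = 1))

  # 3 of 10 entered cells are margins
  codes2 <- codes
  codes2[5, c(4, 7, 9)] <- 3L
  g2 <- land_grid(codes2, 30, classes = classes)
  comp <- landcover_composition(lcp_set(list(p), dim = c(10, 20)), g2)
  expect_equal(comp[["margin"]], 0.3)
  expect_equal(sum(comp), 1)
  # the first cell of a path contributes nothing
  codes3 <- codes
  codes3[5, 1] <- 8L  # water under the start point only
  g3 <- land_grid(codes3, 30, classes = classes)
  comp3 <- landcover_composition(lcp_set(list(p), dim = c(10, 20)), g3)
  expect_false("water" %in% names(comp3))
})

test_that("per-iteration metrics aggregate into mean and sd rows", {
  dims <- c(10, 20)
  inner <- matrix(TRUE, dims[1], dims[2])
  p1 <- hand_path(cbind(5, 1:11), iteration = 1L)
  p2 <- hand_path(cbind(3, 1:6), iteration = 2L)
  set <- lcp_set(list(p1, p2), dim = dims)
  m <- connectivity_metrics(set, inner)
  expect_equal(nrow(m), 2)
  expect_equal(m$total_path_length_km, c(0.3, 0.15))
  s <- summarise_metrics(m)
  expect_equal(s$total_path_length_km[s$stat == "mean"], 0.225)
  expect_equal(s$total_path_length_km[s$stat == "sd"],
               sd(c(0.3, 0.15)))
})

test_that("metrics reject a misaligned inner mask", {
  set <- lcp_set(list(hand_path(cbind(1, 1:3))), dim = c(5, 5))
  expect_error(unique_path_length(set, matrix(TRUE, 4, 5)), "not aligned")
  expect_error(mean_distance_to_path(set, matrix(TRUE, 5, 4)), "not aligned")
})
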