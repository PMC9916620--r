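test_that("linear load scaling reproduces the published pomegranate example", {
  # printed per-acre loads: pomegranate 2,220,400,221 vs urban 1,500,895,028
  raw <- load_to_resistance(2220400221, 1500895028, 8, round = FALSE)
  expect_equal(raw / 8, 1.47, tolerance = 0.01)     # the load ratio
  expect_equal(raw, 11.76, tolerance = 0.01)        # raw resistance
  expect_identical(load_to_resistance(2220400221, 1500895028, 8), 12L)
})

test_that("the urban anchor maps to itself and zero load floors at 1", {
  for (a in c(1, 7, 8, 9, 50, 100))
    expect_identical(load_to_resistance(1500895028, 1500895028, a),
                     as.integer(a))
  expect_identical(load_to_resistance(0, 1500895028, 8), 1L)
  expect_identical(load_to_resistance(1e20, 1500895028, 8), 100L)
  expect_error(load_to_resistance(1, 0, 8), "positive")
})

test_that("raw resistance is linear in the class load before rounding", {
  r1 <- load_to_resistance(3e8, 1.5e9, 8, round = FALSE)
  r10 <- load_to_resistance(3e9, 1.5e9, 8, round = FALSE)
  expect_equal(r10, 10 * r1)
})

test_that("rounding is half-up to the nearest whole number", {
  expect_identical(load_to_resistance(11.5, 8, 8), 12L)  # ratio 1.4375 * 8
  expect_identical(load_to_resistance(1.4375e9, 1e9, 8), 12L) # raw 11.5
  expect_identical(load_to_resistance(1.4374e9, 1e9, 8), 11L)
})

test_that("the packaged resistance table matches its published statistics", {
  tab <- table1_resistance()
  ag <- tab[tab$agriculture == "Y", ]
  expect_equal(nrow(ag), 24)
  expect_equal(round(mean(ag$low), 1), 19.4)
  expect_equal(round(mean(ag$medium), 1), 22.0)
  # the Other row is the rounded mean of the crop rows at each level
  expect_equal(round(mean(ag$medium)),
               tab$medium[tab$land_class == "Other"])
  expect_true(all(tab$low <= tab$medium & tab$medium <= tab$high))
  expect_true(all(tab$low >= 1 & tab$high <= 100))
  expect_equal(unlist(tab[tab$land_class == "Water",
                          c("low", "medium", "high")], use.names = FALSE),
               c(100, 100, 100))
})

test_that("build_resistance_table computes, overrides and averages", {
  loads <- data.frame(land_class = c("CropA", "CropB", "Urban"),
                      low = c(10, 20, 8) * 1e8,
                      medium = c(10, 20, 8) * 1e8,
                      high = c(10, 20, 8) * 1e8)
  rt <- build_resistance_table(loads, urban_class = "Urban")
  # medium: 10/8 * 8 = 10 and 20/8 * 8 = 20; Other = mean(10, 20) = 15
  expect_identical(rt$medium[rt$land_class == "CropA"], 10L)
  expect_identical(rt$medium[rt$land_class == "CropB"], 20L)
  expect_identical(rt$medium[rt$land_class == "Other"], 15L)
  expect_identical(rt$medium[rt$land_class == "Urban"], 8L)
  expect_identical(unique(rt$provenance[rt$land_class %in%
                                          c("CropA", "CropB", "Other")]),
                   "computed")
  # expert overrides replace computed entries and are flagged
  expect_identical(rt$provenance[rt$land_class == "Water"], "expert")
  expect_identical(rt$medium[rt$land_class == "Agricultural Margin"], 15L)
  expect_true(all(rt$low <= rt$medium & rt$medium <= rt$high))
})

test_that("an overrides-only table passes through flagged as expert", {
  ov <- data.frame(land_class = c("x", "y"), low = c(1L, 5L),
                   medium = c(2L, 6L), high = c(3L, 7L))
  rt <- build_resistance_table(data.frame(), overrides = ov)
  expect_equal(nrow(rt), 2)
  expect_identical(unique(rt$provenance), "expert")
  bad <- data.frame(land_class = "x", low = 0L, medium = 2L, high = 3L)
  expect_error(build_resistance_table(data.frame(), overrides = bad),
               "\\[1, 100\\]")
})

test_that("margin scenarios recode exactly the margin cells", {
  ls <- small_landscape()
  g <- ls$grid
  roles <- setNames(g$classes$role, g$classes$code)
  n_margin <- sum(roles[as.character(g$codes)] == "margin")
  n_natural <- sum(roles[as.character(g$codes)] == "natural")

  expect_identical(apply_margin_scenario(g, "current"), g)

  res <- apply_margin_scenario(g, "restored")
  roles_res <- roles[as.character(res$codes)]
  expect_equal(sum(roles_res == "margin"), 0)
  expect_equal(sum(roles_res == "natural"), n_natural + n_margin)
  untouched <- roles[as.character(g$codes)] != "margin"
  expect_identical(res$codes[untouched], g$codes[untouched])

  none <- apply_margin_scenario(g, "none")
  roles_none <- roles[as.character(none$codes)]
  expect_equal(sum(roles_none == "margin"), 0)
  # former margins all became crop, everything else untouched
  was_margin <- roles[as.character(g$codes)] == "margin"
  expect_true(all(roles_none[was_margin] == "crop"))
  expect_identical(none$codes[!was_margin], g$codes[!was_margin])
})

test_that("margin elimination assigns the nearest crop, row-major on ties", {
  # 7x7 grid: two 2x2 parcels of different crops, margins between them
  classes <- rbind(base_class_table(c("Left", "Right")))
  codes <- matrix(2L, 7, 7)        # grassland
  codes[3:4, 1:2] <- 11L           # Left parcel
  codes[3:4, 6:7] <- 12L           # Right parcel
  codes[2:5, 3] <- 3L              # margin strip east of Left
  codes[2:5, 5] <- 3L              # margin strip west of Right
  codes[2:5, 4] <- 3L              # middle strip: equidistant cells
  g <- land_grid(codes, 30, classes = classes)
  none <- apply_margin_scenario(g, "none")
  # strips adjacent to one parcel take that parcel's crop
  expect_true(all(none$codes[3:4, 3] == 11L))
  expect_true(all(none$codes[3:4, 5] == 12L))
  # the middle column is equidistant (2 cells from both parcels); the
  # row-major tie-break picks the Left parcel cell (lower flat index)
  expect_true(all(none$codes[3:4, 4] == 11L))

  g_nocrop <- land_grid(matrix(c(2L, 3L, 2L, 3L), 2), 30,
                        classes = base_class_table(character(0)))
  expect_error(apply_margin_scenario(g_nocrop, "none"), "no crop")
})

test_that("rasterization looks up the published values and keeps nodata", {
  tab <- table1_resistance()
  classes <- base_class_table(c("Pomegranates"))
  codes <- matrix(c(11L, 8L, 11L, NA), 2)
  g <- land_grid(codes, 30, classes = classes)
  rg <- rasterize_resistance(g, tab, "medium")
  expect_equal(rg$values[1, 1], 12)   # pomegranate medium
  expect_equal(rg$values[2, 1], 100)  # water
  expect_true(is.na(rg$values[2, 2]))
  expect_equal(sum(!is.na(rg$values)), 3)

  uniform <- land_grid(matrix(1L, 3, 3), 30,
                       classes = base_class_table(character(0)))
  expect_true(all(rasterize_resistance(uniform, tab, "low")$values == 1))

  missing <- land_grid(matrix(c(1L, 9L), 2, 2), 30,
                       classes = base_class_table(character(0)))
  tab2 <- tab[tab$land_class != "Other", ]
  expect_error(rasterize_resistance(missing, tab2, "low"), "Other")
})

test_that("restored-margin surfaces are pointwise <= current at every level", {
  ls <- small_landscape()
  tabs <- generate_pesticide_tables(ls$grid, pesticide_config(), seed = 1)
  scen <- collapse_to_scenarios(
    toxic_load_annual(tabs$use_records, tabs$ld50, tabs$acreage))
  rt <- suppressWarnings(build_resistance_table(scen))
  for (lv in c("low", "medium", "high")) {
    cur <- rasterize_resistance(apply_margin_scenario(ls$grid, "current"),
                                rt, lv)
    res <- rasterize_resistance(apply_margin_scenario(ls$grid, "restored"),
                                rt, lv)
    expect_true(all(res$values <= cur$values, na.rm = TRUE))
  }
})

test_that("a rasterized table round-trips back to the class map", {
  ls <- small_landscape()
  tabs <- generate_pesticide_tables(ls$grid, pesticide_config(), seed = 1)
  scen <- collapse_to_scenarios(
    toxic_load_annual(tabs$use_records, tabs$ld50, tabs$acreage))
  rt <- suppressWarnings(build_resistance_table(scen))
  rg <- rasterize_resistance(ls$grid, rt, "medium")
  name_of <- setNames(ls$grid$classes$name, ls$grid$classes$code)
  value_of <- setNames(rt$medium, rt$land_class)
  expect_equal(rg$values,
               matrix(as.numeric(value_of[name_of[as.character(ls$grid$codes)]]),
                      nrow(ls$grid$codes)))
  expect_true(all(rg$values >= 1 & rg$values <= 100, na.rm = TRUE))
})
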