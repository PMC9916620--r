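test_that("unit conversions follow the published constants", {
  expect_identical(pounds_to_micrograms(1), 453592370)
  expect_identical(pounds_to_micrograms(0), 0)
  expect_identical(pounds_to_micrograms(2), 907184740)
  expect_error(pounds_to_micrograms(-1), "non-negative")

  # printed worked example: micrograms of spinosad over its contact LD50
  expect_equal(lethal_doses(1183052498279, 0.0029), 407949137337493,
               tolerance = 1e-9)
  expect_identical(lethal_doses(0, 0.0029), 0)
  expect_identical(lethal_doses(5, 5), 1)
  expect_error(lethal_doses(1, 0), "positive")

  expect_identical(per_acre_load(1000, 10), 100)
  expect_identical(per_acre_load(0, 552724), 0)
  expect_equal(per_acre_load(4.0794913733749e14, 552724), 7.3807e8,
               tolerance = 1e-4)
  expect_error(per_acre_load(1, 0), "positive")
})

test_that("class annual load composes the three conversions additively", {
  tabs <- toy_tables()
  # factors cancel: 1 lb at LD50 = conversion factor over 1 acre -> 1.0
  rec1 <- data.frame(chemical = "X", land_class = "c", year = 2014,
                     pounds = 1)
  ld1 <- data.frame(chemical = "X", ld50_ug_per_bee = 453592370)
  ac1 <- data.frame(land_class = "c", acres = 1)
  expect_equal(class_annual_load(rec1, ld1, ac1, "c", 2014), 1.0)

  # hand calculation oracle, chemical by chemical, for 2014
  hand <- sum(vapply(c("A", "B", "C"), function(ch) {
    r <- tabs$use_records
    lbs <- r$pounds[r$chemical == ch & r$year == 2014]
    ld <- tabs$ld50$ld50_ug_per_bee[tabs$ld50$chemical == ch]
    lbs * 453592370 / ld / 1000
  }, 1))
  expect_equal(class_annual_load(tabs$use_records, tabs$ld50, tabs$acreage,
                                 "Almonds", 2014), hand, tolerance = 1e-12)

  # additivity: two chemicals each worth 100 doses/acre
  rec2 <- data.frame(chemical = c("X", "Y"), land_class = "c", year = 1,
                     pounds = c(100, 100))
  ld2 <- data.frame(chemical = c("X", "Y"),
                    ld50_ug_per_bee = rep(453592370, 2))
  expect_equal(class_annual_load(rec2, ld2, ac1, "c", 1), 200)
})

test_that("missing lookups fail loudly with the offender named", {
  tabs <- toy_tables()
  ld <- tabs$ld50[tabs$ld50$chemical != "B", ]
  expect_error(class_annual_load(tabs$use_records, ld, tabs$acreage,
                                 "Almonds", 2014), "B")
  ac <- tabs$acreage[tabs$acreage$land_class != "Almonds", ]
  expect_error(class_annual_load(tabs$use_records, tabs$ld50, ac,
                                 "Almonds", 2014), "Almonds")
})

test_that("loads scale linearly with pounds applied", {
  tabs <- toy_tables()
  base <- class_annual_load(tabs$use_records, tabs$ld50, tabs$acreage,
                            "Almonds", 2015)
  tabs$use_records$pounds <- tabs$use_records$pounds * 2
  expect_equal(class_annual_load(tabs$use_records, tabs$ld50, tabs$acreage,
                                 "Almonds", 2015), 2 * base)
})

test_that("annual table fills silent years with zero load", {
  tabs <- toy_tables()
  extra <- data.frame(chemical = "A", land_class = "Urban", year = 2014,
                      pounds = 5)
  recs <- rbind(tabs$use_records, extra)
  ann <- toxic_load_annual(recs, tabs$ld50, tabs$acreage)
  urban <- ann[ann$land_class == "Urban", ]
  expect_equal(nrow(urban), 3)
  expect_equal(urban$doses_per_acre[urban$year %in% 2015:2016], c(0, 0))
  expect_gt(urban$doses_per_acre[urban$year == 2014], 0)
})

test_that("structural pest control records are excluded", {
  tabs <- toy_tables()
  spc <- data.frame(chemical = "A", land_class = "Structural Pest Control",
                    year = 2014:2016, pounds = 99)
  ann <- toxic_load_annual(rbind(tabs$use_records, spc), tabs$ld50,
                           tabs$acreage)
  expect_false("Structural Pest Control" %in% ann$land_class)
})

test_that("scenario collapse takes min, median, max of the three years", {
  ann <- data.frame(land_class = rep(c("a", "b", "c"), each = 3),
                    year = rep(1:3, 3),
                    doses_per_acre = c(10, 5, 7, 4, 4, 4, 3, 0, 9))
  sc <- collapse_to_scenarios(ann)
  expect_equal(unlist(sc[sc$land_class == "a", c("low", "medium", "high")],
                      use.names = FALSE), c(5, 7, 10))
  expect_equal(unlist(sc[sc$land_class == "b", c("low", "medium", "high")],
                      use.names = FALSE), c(4, 4, 4))
  expect_equal(unlist(sc[sc$land_class == "c", c("low", "medium", "high")],
                      use.names = FALSE), c(0, 3, 9))
  expect_true(all(sc$low <= sc$medium & sc$medium <= sc$high))
})

test_that("scenario collapse rejects year counts other than three", {
  ann <- data.frame(land_class = "a", year = 1:2, doses_per_acre = c(1, 2))
  expect_error(collapse_to_scenarios(ann), "exactly 3")
})

test_that("classes with no applications in any year are dropped with a warning", {
  ann <- data.frame(land_class = rep(c("a", "zero"), each = 3),
                    year = rep(1:3, 2),
                    doses_per_acre = c(1, 2, 3, 0, 0, 0))
  expect_warning(sc <- collapse_to_scenarios(ann), "zero")
  expect_equal(sc$land_class, "a")
})

test_that("randomized additivity: class load equals the sum of its parts", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      n <- sample(3:6, 1)
      recs <- data.frame(chemical = paste0("chem", seq_len(n)),
                         land_class = "c", year = 2000,
                         pounds = runif(n, 0, 50))
      ld <- data.frame(chemical = recs$chemical,
                       ld50_ug_per_bee = runif(n, 0.001, 2))
      ac <- data.frame(land_class = "c", acres = runif(1, 10, 1e5))
      parts <- vapply(seq_len(n), function(i)
        class_annual_load(recs[i, ], ld, ac, "c", 2000), 1)
      expect_equal(class_annual_load(recs, ld, ac, "c", 2000), sum(parts),
                   tolerance = 1e-12)
    }
  })
})
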