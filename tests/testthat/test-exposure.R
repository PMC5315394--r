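# Buffer crop indices: exact clipping vs closed forms and the MC oracle.

test_that("full containment and zero-crop landscapes give 100 and 0", {
  lay <- square_layer("Irrigated")
  ci <- crop_index(5000, 5000, lay, radius_m = 1000)
  expect_equal(ci$gci, 100)
  expect_equal(ci$irrigated, 100)
  expect_equal(unlist(ci[c("rice", "vineyards", "fruits", "olives",
                           "heterogeneous")]), rep(0, 5), ignore_attr = TRUE)

  lay0 <- square_layer("NonCrop")
  expect_equal(crop_index(5000, 5000, lay0, radius_m = 1000)$gci, 0)
})

test_that("buffer centred on a half-plane boundary splits 50/50", {
  lay <- halfplane_layer("Irrigated", "NonCrop", split_x = 5000)
  ci <- crop_index(5000, 5000, lay, radius_m = 1000)
  expect_equal(ci$irrigated, 50, tolerance = 0.5 / 50)
  expect_equal(ci$gci, ci$irrigated)
  # MC oracle sees the same half-plane
  o <- crop_index_oracle(5000, 5000, lay, radius_m = 1000, n_samples = 1e5,
                         seed = 3)
  expect_lt(abs(o$irrigated - 50), 0.5)
})

test_that("gci equals the sum of subcategory indices", {
  cfg <- tiny_config()
  ls <- generate_landscape(cfg, 5)
  pts <- generate_population(ls, 200, cfg, 6)
  ok <- pts$geocode_valid
  ci <- crop_index(pts$x[ok], pts$y[ok], ls$land_cover)
  expect_true(all(abs(ci$gci - rowSums(ci[, -1])) < 1e-6))
  expect_true(all(ci$gci >= 0 & ci$gci <= 100))
})

test_that("exact index agrees with the Monte-Carlo oracle on random draws", {
  cfg <- tiny_config()
  set.seed(99)
  for (rep in 1:6) {
    ls <- generate_landscape(cfg, 100 + rep)
    px <- runif(1, 2000, 18000); py <- runif(1, 2000, 18000)
    exact <- crop_index(px, py, ls$land_cover, radius_m = 1000)
    mc <- crop_index_oracle(px, py, ls$land_cover, radius_m = 1000,
                            n_samples = 1e5, seed = rep)
    expect_lt(abs(exact$gci - mc$gci), 1)
    for (cc in c("irrigated", "heterogeneous"))
      expect_lt(abs(exact[[cc]] - mc[[cc]]), 1)
  }
})

test_that("index is invariant under joint translation", {
  lay <- halfplane_layer("Olives", "NonCrop", split_x = 4000)
  base <- crop_index(4300, 5000, lay, radius_m = 800)
  shift <- c(13000, -7000)
  lay2 <- poly_layer(lapply(lay$polygons, function(p)
    cbind(p[, 1] + shift[1], p[, 2] + shift[2])), lay$props)
  moved <- crop_index(4300 + shift[1], 5000 + shift[2], lay2, radius_m = 800)
  expect_equal(moved$olives, base$olives, tolerance = 1e-9)
})

test_that("index follows the concentric-disc closed form and shrinks with radius", {
  # crop disc of radius 500 centred on the buffer: index = 100 (500/r)^2
  L <- 20000
  disc <- disc_ring(10000, 10000, 500, n = 1024)
  lay <- poly_layer(list(disc), data.frame(category = "Fruits"))
  prev <- Inf
  for (r in c(600, 800, 1000, 1500, 2500)) {
    ci <- crop_index(10000, 10000, lay, radius_m = r)
    expect_equal(ci$fruits, 100 * (500 / r)^2, tolerance = 0.01)
    expect_lt(ci$fruits, prev)
    prev <- ci$fruits
  }
})

test_that("degenerate inputs error or warn as documented", {
  lay <- square_layer("Irrigated")
  expect_error(crop_index(5000, 5000, lay, radius_m = 0), "positive")
  expect_error(crop_index_oracle(5000, 5000, lay, n_samples = 100), "1e4|10000")
  empty <- poly_layer(list(), data.frame(category = character(0)))
  expect_warning(ci <- crop_index(5000, 5000, empty), "empty")
  expect_equal(ci$gci, 0)
})

test_that("overlapping same-category polygons are not double counted", {
  # two identical Irrigated squares stacked on each other
  sq <- cbind(c(0, 10000, 10000, 0), c(0, 0, 10000, 10000))
  lay <- poly_layer(list(sq, sq),
                    data.frame(category = c("Irrigated", "Irrigated")))
  expect_warning(ci <- crop_index(5000, 5000, lay, radius_m = 1000),
                 "overlap")
  expect_lt(abs(ci$irrigated - 100), 1)
  expect_lte(ci$gci, 100)
})

test_that("scale_for_model divides the index by 10", {
  expect_equal(scale_for_model(0), 0)
  expect_equal(scale_for_model(100), 10)
  expect_equal(scale_for_model(25), 2.5)
  ci <- crop_index(5000, 5000, square_layer("Irrigated"))
  expect_equal(scale_for_model(ci), 10)
})
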