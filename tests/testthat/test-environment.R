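# Environment classification rules, distance computation and the D sweep.

test_that("nearest facility distance matches simple geometry", {
  fac <- data.frame(x = c(0, 10000), y = c(0, 0))
  expect_equal(nearest_facility_distance(0, 0, fac), 0)
  expect_equal(nearest_facility_distance(3000, 0, fac), 3000)
  expect_equal(nearest_facility_distance(7000, 0, fac), 3000)
  expect_error(nearest_facility_distance(0, 0, data.frame(x = numeric(0),
                                                          y = numeric(0))),
               "empty")
})

test_that("nearest facility distance equals the exhaustive oracle", {
  set.seed(8)
  fac <- data.frame(x = runif(60, 0, 20000), y = runif(60, 0, 20000))
  px <- runif(500, 0, 20000); py <- runif(500, 0, 20000)
  expect_equal(nearest_facility_distance(px, py, fac),
               nearest_oracle(px, py, fac$x, fac$y), tolerance = 1e-12)
})

test_that("classification applies the five-category rule", {
  urb <- poly_layer(list(rect_ring_test(0, 0, 2000, 2000)),
                    data.frame(population = 50000))
  fac <- data.frame(x = 1000, y = 1000)
  cl <- function(x, y, D = 2000)
    as.character(classify_environment(x, y, fac, urb, D_m = D)$category)
  expect_equal(cl(1000, 1500), "intersection")          # u, d = 500 <= D
  expect_equal(cl(2500, 1000, D = 2000), "industrial")  # !u, d = 1500
  expect_equal(cl(4000, 1000, D = 2000), "ring")        # !u, 2000 < 3000 <= 5000
  expect_equal(cl(9000, 1000, D = 2000), "rural")       # d = 8000 > 5000
  # urban subjects never fall in the ring
  urb2 <- poly_layer(list(rect_ring_test(4000, 0, 6000, 2000)),
                     data.frame(population = 50000))
  expect_equal(as.character(classify_environment(5000, 1000, fac, urb2,
                                                 D_m = 2000)$category), "urban")
  expect_error(classify_environment(0, 0, fac, urb, D_m = 6000), "outer")
})

test_that("boundary conventions: d <= D exposed, d > outer rural, border urban", {
  urb <- poly_layer(list(rect_ring_test(0, 0, 1000, 1000)),
                    data.frame(population = 20000))
  fac <- data.frame(x = 0, y = 5000)
  # point exactly at distance D
  r <- classify_environment(0, 3000, fac, urb, D_m = 2000)
  expect_equal(as.character(r$category), "industrial")
  # point exactly at outer
  r <- classify_environment(0, 10000, fac, urb, D_m = 2000, outer_m = 5000)
  expect_equal(as.character(r$category), "ring")
  # point on the urban polygon boundary counts as inside
  r <- classify_environment(1000, 500, fac, urb, D_m = 100)
  expect_true(r$in_urban)
  expect_equal(as.character(r$category), "urban")
})

test_that("small urban polygons below the population threshold do not count", {
  urb <- poly_layer(list(rect_ring_test(0, 0, 1000, 1000)),
                    data.frame(population = 5000))
  fac <- data.frame(x = 20000, y = 20000)
  r <- classify_environment(500, 500, fac, urb, D_m = 2000,
                            urban_pop_threshold = 10000)
  expect_false(r$in_urban)
  expect_equal(as.character(r$category), "rural")
})

test_that("classification matches the rule oracle over random points and D values", {
  cfg <- tiny_config()
  ls <- generate_landscape(cfg, 91)
  set.seed(17)
  px <- runif(400, 0, cfg$extent_m); py <- runif(400, 0, cfg$extent_m)
  for (D in c(1000, 2500, 5000)) {
    got <- as.character(classify_environment(px, py, ls$facilities,
                                             ls$urban_areas, D_m = D)$category)
    want <- classify_oracle(px, py, ls$facilities, ls$urban_areas,
                            D_m = D, outer_m = 5000)
    expect_equal(got, want)
  }
})

test_that("exposed set grows with D and urban status is D-invariant", {
  cfg <- tiny_config()
  ls <- generate_landscape(cfg, 92)
  set.seed(18)
  px <- runif(500, 0, cfg$extent_m); py <- runif(500, 0, cfg$extent_m)
  prev <- NULL; prev_u <- NULL
  for (D in c(1000, 1500, 2000, 3000, 5000)) {
    r <- classify_environment(px, py, ls$facilities, ls$urban_areas, D_m = D)
    exposed <- which(r$category %in% c("industrial", "intersection"))
    if (!is.null(prev)) expect_true(all(prev %in% exposed))
    if (!is.null(prev_u)) expect_identical(r$in_urban, prev_u)
    prev <- exposed; prev_u <- r$in_urban
    # exhaustive and exclusive: every point classified exactly once
    expect_false(anyNA(r$category))
  }
  # D = outer: the ring is empty by construction
  r <- classify_environment(px, py, ls$facilities, ls$urban_areas,
                            D_m = 5000, outer_m = 5000)
  expect_equal(sum(r$category == "ring"), 0)
})

test_that("d_sweep refits per distance and records failures per row", {
  cfg <- tiny_config(params = null_params())
  sim <- simulate_study(cfg, 7)
  sw <- d_sweep(sim$data, sim$landscape$facilities, sim$landscape$urban_areas,
                D_list = c(1500, 3000), outer_m = 5000)
  expect_true(all(c("D_m", "term", "or", "error") %in% names(sw)))
  expect_setequal(unique(sw$D_m), c(1500, 3000))
  expect_true(all(is.na(sw$error)))
  expect_true(all(sw$or[!is.na(sw$or)] > 0))
})
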