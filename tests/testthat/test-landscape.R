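# Synthetic landscape, population and outcome generators.

test_that("land-cover and tract layers partition the extent", {
  cfg <- tiny_config()
  ls <- generate_landscape(cfg, 21)
  a_ext <- cfg$extent_m^2
  expect_lt(abs(sum(layer_areas(ls$land_cover)) - a_ext) / a_ext, 1e-6)
  expect_lt(abs(sum(layer_areas(ls$tracts)) - a_ext) / a_ext, 1e-6)
  expect_true(validate_landscape(ls))
  expect_true(all(ls$tracts$props$ses >= cfg$ses_range[1] &
                  ls$tracts$props$ses <= cfg$ses_range[2]))
})

test_that("degenerate mixture labels every cell NonCrop", {
  w <- setNames(c(rep(0, 6), 1), c(crop_categories(), "NonCrop"))
  cfg <- tiny_config(crop_weights = w)
  ls <- generate_landscape(cfg, 3)
  expect_true(all(ls$land_cover$props$category == "NonCrop"))
  pts <- generate_population(ls, 50, cfg, 4)
  ok <- pts$geocode_valid
  expect_true(all(crop_index(pts$x[ok], pts$y[ok], ls$land_cover)$gci == 0))
})

test_that("generation is deterministic: same seed gives byte-identical layers", {
  cfg <- tiny_config()
  d1 <- file.path(tempdir(), "ls1"); d2 <- file.path(tempdir(), "ls2")
  write_landscape(generate_landscape(cfg, 77), d1)
  write_landscape(generate_landscape(cfg, 77), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  d3 <- file.path(tempdir(), "ls3")
  write_landscape(generate_landscape(cfg, 78), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "landcover.geojson"))),
                         unname(tools::md5sum(file.path(d3, "landcover.geojson")))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("GeoJSON round trip preserves geometry and properties", {
  cfg <- tiny_config()
  ls <- generate_landscape(cfg, 13)
  f <- tempfile(fileext = ".geojson")
  write_geojson(ls$land_cover, f)
  back <- read_geojson(f)
  expect_equal(length(back), length(ls$land_cover))
  expect_equal(back$props$category, ls$land_cover$props$category)
  expect_equal(back$polygons[[5]], ls$land_cover$polygons[[5]],
               ignore_attr = TRUE, tolerance = 1e-9)
  fp <- tempfile(fileext = ".geojson")
  write_geojson(ls$facilities, fp)
  fac <- read_geojson(fp)
  expect_equal(fac$x, ls$facilities$x, tolerance = 1e-9)
  expect_equal(fac$group, ls$facilities$group)
  unlink(c(f, fp))
})

test_that("population respects size, validity fraction and urban concentration", {
  cfg <- tiny_config()
  ls <- generate_landscape(cfg, 31)

  p0 <- generate_population(ls, 100, tiny_config(invalid_fraction = 0), 32)
  expect_equal(nrow(p0), 100)
  expect_true(all(p0$geocode_valid))
  expect_error(generate_population(ls, 0, cfg, 1), ">= 1")

  p <- generate_population(ls, 10000, cfg, 33)
  n_invalid <- sum(!p$geocode_valid)
  expect_gte(n_invalid, qbinom(0.005, 10000, 0.02))
  expect_lte(n_invalid, qbinom(0.995, 10000, 0.02))
  expect_true(all(is.na(p$x[!p$geocode_valid])))
  expect_true(all(p$x[p$geocode_valid] >= 0 &
                  p$x[p$geocode_valid] <= cfg$extent_m))

  # urban concentration beats the urban area share
  urb_share <- sum(layer_areas(ls$urban_areas)) / cfg$extent_m^2
  inside <- rep(FALSE, nrow(p))
  for (ring in ls$urban_areas$polygons)
    inside <- inside | pip_oracle(p$x, p$y, ring)
  expect_gt(mean(inside[p$geocode_valid]), urb_share * 2)

  # region marginal roughly uniform as configured
  expect_true(all(abs(table(p$region) / 10000 - 1 / 3) < 0.03))
})

test_that("null outcome model selects cases independently of exposure", {
  cfg <- tiny_config(params = null_params())
  ls <- generate_landscape(cfg, 41)
  pool <- generate_population(ls, 3000, cfg, 42)
  prof <- exposure_profiles(pool, ls, cfg)
  diffs <- sapply(1:20, function(i) {
    oc <- assign_outcomes(pool, prof, cfg$params, 150, 500 + i)
    mean(prof$gci[match(oc$cases$id, pool$id)]) -
      mean(prof$gci[pool$geocode_valid], na.rm = TRUE)
  })
  # mean difference across replicates compatible with zero
  expect_lt(abs(mean(diffs)) / (sd(diffs) / sqrt(length(diffs))), 4)
})

test_that("a positive crop effect raises mean case exposure", {
  cfg <- tiny_config(params = true_params(or_gci_per10 = 2, or_ses_q = c(1, 1, 1),
                                          or_env = c(1, 1, 1, 1),
                                          region_sd = 0))
  ls <- generate_landscape(cfg, 51)
  pool <- generate_population(ls, 3000, cfg, 52)
  prof <- exposure_profiles(pool, ls, cfg)
  diffs <- sapply(1:10, function(i) {
    oc <- assign_outcomes(pool, prof, cfg$params, 150, 600 + i)
    mean(prof$gci[match(oc$cases$id, pool$id)]) -
      mean(prof$gci[match(oc$pool$id, pool$id)], na.rm = TRUE)
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("subgroup labels follow the registry multinomial", {
  cfg <- tiny_config()
  ls <- generate_landscape(cfg, 61)
  pool <- generate_population(ls, 4000, cfg, 62)
  prof <- exposure_profiles(pool, ls, cfg)
  labs <- unlist(lapply(1:10, function(i) {
    assign_outcomes(pool, prof, cfg$params, 200, 700 + i)$cases$subgroup
  }))
  share <- mean(labs == "astrocytoma")
  truth <- 258 / 714
  expect_lt(abs(share - truth), 4 * sqrt(truth * (1 - truth) / length(labs)))
  expect_error(assign_outcomes(pool, prof, cfg$params, 4000, 1), "pool")
})

test_that("outcome assignment is deterministic given the seed", {
  cfg <- tiny_config()
  ls <- generate_landscape(cfg, 71)
  pool <- generate_population(ls, 2000, cfg, 72)
  prof <- exposure_profiles(pool, ls, cfg)
  a <- assign_outcomes(pool, prof, cfg$params, 100, 9)
  b <- assign_outcomes(pool, prof, cfg$params, 100, 9)
  expect_identical(a$cases$id, b$cases$id)
  expect_identical(a$cases$subgroup, b$cases$subgroup)
})
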