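test_that("generation is a pure function of the recipe", {
  r <- farm_recipe(seed = 7)
  a <- generate_soil_raster(r)
  b <- generate_soil_raster(r)
  expect_identical(a$raster, b$raster)
  expect_identical(a$grid$cells, b$grid$cells)
  fa <- synthetic_farm(r)
  fb <- synthetic_farm(r)
  expect_identical(fa$catalog$Y, fb$catalog$Y)
  expect_identical(fa$catalog$W, fb$catalog$W)
  # a different seed gives a different farm
  expect_false(identical(a$grid$cells, generate_soil_raster(farm_recipe(seed = 8))$grid$cells))
})

test_that("generation leaves the global RNG stream untouched", {
  set.seed(123)
  r1 <- runif(3)
  set.seed(123)
  invisible(synthetic_farm(farm_recipe(seed = 99)))
  r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("soil rasters cover the grid with the requested classes", {
  gen <- generate_soil_raster(farm_recipe(seed = 3, n_classes = 5, blob_count = 12))
  expect_identical(dim(gen$grid$cells), c(18L, 18L))
  expect_false(anyNA(gen$raster))
  expect_identical(sort(unique(as.integer(gen$grid$cells))), 1:5)
  expect_true(all(gen$raster %in% 1:5))
  # degenerate class count: uniform farm
  uni <- generate_soil_raster(farm_recipe(seed = 3, n_classes = 1, blob_count = 4,
    class_weights = 1))
  expect_true(all(uni$grid$cells == 1L))
  expect_error(
    generate_soil_raster(farm_recipe(seed = 1, n_rows = 2, n_cols = 2,
      fine_factor = 1, blob_count = 5)),
    "blob_count"
  )
})

test_that("derived yields respect the water-balance rules", {
  farm <- default_test_farm()
  cat <- farm$catalog
  freqs <- cat$frequencies
  irrigated <- which(freqs$events > 0L)
  never <- which(freqs$events == 0L)
  S <- nrow(cat$seeds)
  J <- nrow(cat$soils)

  # fallow rows are identically zero
  for (s in seq_len(S)) {
    i <- option_index(never, s)
    expect_true(all(cat$W[i, ] == 0) && all(cat$Y[i, ] == 0))
  }
  # yield envelope, ceiling attained by the top extravagant hybrid
  expect_true(all(cat$Y >= 0 & cat$Y <= 18.81 + 1e-9))
  expect_equal(max(cat$Y), 18.81)
  expect_identical(
    cat$seeds$name[option_rs(which(cat$Y == max(cat$Y), arr.ind = TRUE)[1, 1])$s],
    "extravagant_3"
  )
  # yield nonincreasing as the irrigation interval grows, for every pair
  by_interval <- irrigated[order(freqs$interval_days[irrigated])]
  for (s in seq_len(S)) {
    for (j in seq_len(J)) {
      ys <- cat$Y[option_index(by_interval, rep(s, length(by_interval))), j]
      expect_true(all(diff(ys) <= 1e-9))
    }
  }
  # sand must be irrigated at least weekly for full yield: weekly beats
  # four-weekly on sand for every seed
  weekly <- which(freqs$label == "weekly")
  fourw <- which(freqs$label == "four_weekly")
  sand <- 1
  for (s in seq_len(S)) {
    expect_gte(cat$Y[option_index(weekly, s), sand], cat$Y[option_index(fourw, s), sand])
  }
})

test_that("every instance admits the all-fallow plan", {
  # a water allotment barely above the pre-irrigation commitment leaves no
  # room to irrigate, but the all-fallow plan must remain feasible
  pre <- default_economics()$pre_irrigation
  farm <- synthetic_farm(farm_recipe(seed = 5,
    economics = default_economics(water_limit = pre + 1)))
  sol <- solve_farm_model(farm, model_spec("I"))
  expect_identical(sol$status, "optimal")
  expect_true(all(sol$idle))
  expect_equal(sol$objective, -farm$econ$overhead_cost * farm$econ$area)
})

test_that("default economics carry the case-study constants", {
  econ <- default_economics()
  expect_identical(econ$corn_price, 141)
  expect_identical(econ$residue_price, 35)
  expect_identical(econ$water_price, 0.073)
  expect_identical(econ$gamma, 0.6)
  expect_identical(econ$beta, 0.3)
  expect_identical(econ$alpha, 0.5)
  expect_identical(econ$area, 65.56)
  expect_equal(econ$water_limit, 2.5 * 1233.48 / 0.40469, tolerance = 1e-12)
  expect_equal(econ$pre_irrigation, (8 / 12) * 1233.48 / 0.40469, tolerance = 1e-12)
})
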