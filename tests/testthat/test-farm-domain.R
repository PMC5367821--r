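test_that("option index is a bijection over the frequency x seed grid", {
  expect_identical(option_index(1, 1), 1L)
  ids <- outer(1:6, 1:12, option_index)
  expect_identical(sort(as.integer(ids)), 1:72)
  for (i in 1:72) {
    rs <- option_rs(i)
    expect_identical(option_index(rs$r, rs$s), as.integer(i))
  }
  expect_error(option_index(0, 1), "out of range")
  expect_error(option_index(7, 1), "out of range")
  expect_error(option_rs(73), "out of range")
})

test_that("per-unit profit components match hand arithmetic", {
  freqs <- data.frame(id = 1:2, label = c("f1", "never"),
    interval_days = c(7, NA), events = c(10L, 0L))
  seeds <- data.frame(id = 1, name = "s", class = "t", max_yield = 19,
    sensitivity = 1, survival_water = 0)
  soils <- soil_classes(1)
  mk <- function(Y, W, C_f, C_m) {
    management_catalog(freqs, seeds, soils,
      Y = matrix(c(Y, 0), 2, 1), W = matrix(c(W, 0), 2, 1),
      C_f = matrix(c(C_f, 0), 2, 1), C_m = matrix(c(C_m, 0), 2, 1))
  }

  # fallow: every component vanishes
  econ <- default_economics()
  up <- unit_profit(mk(10, 100, 5, 5), econ, i = 2, j = 1, unit_area = 1)
  expect_identical(up$net, 0)

  # residue revenue, alpha = 0.5, beta = 0.3: 10 * 1 * 0.5 * 0.7 * 35 / 0.5
  econ <- default_economics(alpha = 0.5, beta = 0.3, residue_price = 35)
  up <- unit_profit(mk(10, 0, 0, 0), econ, i = 1, j = 1, unit_area = 1)
  expect_equal(up$revenue_residue, 245)

  # grain-only revenue at the case-study yield ceiling
  econ <- default_economics(alpha = 0.5, beta = 1) # beta 1 kills residue
  up <- unit_profit(mk(18.81, 0, 0, 0), econ, i = 1, j = 1, unit_area = 0.2023)
  expect_equal(up$revenue_grain, 18.81 * 0.2023 * 141, tolerance = 1e-12)
  expect_equal(up$revenue_grain, 536.6, tolerance = 1e-3)

  expect_error(unit_profit(mk(1, 1, 1, 1), econ, i = 3, j = 1, unit_area = 1),
    "out of range")
  expect_error(unit_profit(mk(1, 1, 1, 1), econ, i = 1, j = 2, unit_area = 1),
    "out of range")
})

test_that("unit profit is linear in each price and cost", {
  farm <- tiny_farm(42, n_rows = 1, n_cols = 1)
  base <- farm$econ
  for (fld in c("corn_price", "residue_price", "water_price")) {
    f0 <- farm; f1 <- farm; f2 <- farm
    f1$econ[[fld]] <- base[[fld]] + 1
    f2$econ[[fld]] <- base[[fld]] + 2
    v <- vapply(list(f0, f1, f2), function(fm) {
      unit_profit(fm$catalog, fm$econ, 1, 1, fm$grid$unit_area)$net
    }, 0)
    expect_equal(v[3] - v[2], v[2] - v[1], tolerance = 1e-9) # constant slope
  }
})

test_that("stored components always reproduce the net value", {
  for (seed in 1:5) {
    farm <- tiny_farm(seed)
    I <- nrow(farm$catalog$options)
    J <- nrow(farm$catalog$soils)
    for (i in seq_len(I)) {
      for (j in seq_len(J)) {
        up <- unit_profit(farm$catalog, farm$econ, i, j, farm$grid$unit_area)
        net2 <- up$revenue_grain + up$revenue_residue - up$cost_operating -
          up$cost_water - up$cost_irrigation_fixed
        expect_equal(up$net, net2, tolerance = 1e-9)
      }
    }
  }
})

test_that("majority vote integrates fine rasters, ties to the lowest id", {
  expect_identical(
    majority_vote_downsample(matrix(c(2L, 3L, 2L, 5L), 2, 2), 2),
    matrix(2L, 1, 1)
  )
  expect_identical(
    majority_vote_downsample(matrix(4L, 6, 6), 3),
    matrix(4L, 2, 2)
  )
  # oracle: enumerate every 2x2 block over two classes and compare with
  # direct counting under the lowest-id tie rule
  combos <- expand.grid(a = 1:2, b = 1:2, c = 1:2, d = 1:2)
  for (k in seq_len(nrow(combos))) {
    block <- matrix(as.integer(combos[k, ]), 2, 2)
    counts <- table(factor(block, levels = 1:2))
    want <- if (counts[1] >= counts[2]) 1L else 2L
    expect_identical(majority_vote_downsample(block, 2)[1, 1], want)
  }
  expect_error(majority_vote_downsample(matrix(1L, 3, 3), 2), "not divisible")
})

test_that("the land-condition indicator is complete and exclusive", {
  for (seed in 1:5) {
    set.seed(seed)
    cells <- matrix(sample(1:4, 30, replace = TRUE), 5, 6)
    cells[1] <- 4L
    L <- soil_indicator(soil_grid(cells, classes = soil_classes(4)))
    expect_true(all(L %in% c(0L, 1L)))
    expect_identical(rowSums(L), rep(1, 30))
    expect_identical(colSums(L), as.double(tabulate(cells, 4)))
  }
})

test_that("economic parameters are validated", {
  expect_error(default_economics(gamma = 0), "gamma")
  expect_error(default_economics(gamma = 1.2), "gamma")
  expect_error(default_economics(alpha = 1), "alpha")
  expect_error(default_economics(beta = -0.1), "beta")
  expect_error(default_economics(corn_price = -5), "non-negative")
  expect_error(default_economics(corn_price = "x"), "single number")
})

test_that("grid/catalogue constructors reject inconsistent inputs", {
  expect_error(soil_grid(matrix(0L, 2, 2)), ">= 1")
  expect_error(soil_grid(matrix(c(1L, 3L, 1L, 1L), 2, 2),
    classes = soil_classes(2)), "only 2 classes")
  freqs <- irrigation_frequencies()
  seeds <- seed_hybrids()
  soils <- soil_classes(2)
  bad <- matrix(1, 72, 2)
  expect_error(
    management_catalog(freqs, seeds, soils, Y = bad, W = bad, C_f = bad, C_m = bad),
    "zero water and yield"
  )
})
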