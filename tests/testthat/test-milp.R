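test_that("objective coefficients follow the per-unit profit table", {
  farm <- tiny_farm(11, n_rows = 2, n_cols = 3, n_classes = 3)
  ob <- objective_coefficients(farm)
  expect_identical(dim(ob$coefficients), c(6L, nrow(farm$catalog$options)))
  expect_equal(ob$constant, -farm$econ$overhead_cost * farm$econ$area)
  j <- as.integer(t(farm$grid$cells))
  for (u in seq_len(6)) {
    for (i in seq_len(nrow(farm$catalog$options))) {
      expect_equal(
        ob$coefficients[u, i],
        unit_profit(farm$catalog, farm$econ, i, j[u], farm$grid$unit_area)$net,
        tolerance = 1e-12
      )
    }
  }
  # coefficients depend on a unit only through its soil class
  same <- which(outer(j, j, "==") & upper.tri(diag(6)), arr.ind = TRUE)
  for (k in seq_len(nrow(same))) {
    expect_identical(ob$coefficients[same[k, 1], ], ob$coefficients[same[k, 2], ])
  }
})

test_that("infinite bounds drop their constraints; finite ones appear", {
  farm <- tiny_farm(12)
  p0 <- agroplan:::build_problem(farm, model_spec("I"))
  expect_identical(length(p0$b), 0L)
  spec <- model_spec("I", irrigation_budget = 100, operating_budget = 200,
    min_yield = 1, water_limit = 500)
  p4 <- agroplan:::build_problem(farm, spec)
  expect_identical(p4$constraint_names,
    c("irrigation_budget", "operating_budget", "min_yield", "water_limit"))
})

test_that("a single-unit farm enumerates exactly its options", {
  farm <- tiny_farm(13, n_rows = 1, n_cols = 1, n_freq = 2, n_seeds = 1)
  bf <- brute_force_solve(farm)
  expect_identical(bf$solver$nodes, 2L) # two options: irrigate or fallow
  sol <- solve_farm_model(farm)
  expect_same_optimum(sol, bf)
  # best single option by direct inspection
  ob <- objective_coefficients(farm)
  expect_equal(sol$objective, max(ob$coefficients[1, ]) + ob$constant,
    tolerance = 1e-9)
})

test_that("solver matches the enumeration oracle across constraint regimes", {
  mk <- function(seed) {
    regime <- seed %% 5
    if (regime == 0) tiny_farm(seed) # unconstrained
    else if (regime == 1) tiny_farm(seed, water_limit = runif(1, 200, 1500))
    else if (regime == 2) tiny_farm(seed, n_rows = 3, n_cols = 3, n_freq = 2,
      water_limit = runif(1, 200, 1200))
    else if (regime == 3) tiny_farm(seed, irrigation_budget = runif(1, 200, 2000),
      water_limit = runif(1, 300, 1500)) # two constraints: general path
    else tiny_farm(seed, min_yield = runif(1, 1, 12)) # >= constraint
  }
  for (seed in 1:15) {
    farm <- mk(seed)
    sol <- solve_farm_model(farm)
    bf <- brute_force_solve(farm)
    expect_same_optimum(sol, bf)
  }
})

test_that("unattainable yield floors are reported infeasible by both paths", {
  farm <- tiny_farm(21, min_yield = 1e6)
  sol <- solve_farm_model(farm)
  bf <- brute_force_solve(farm)
  expect_identical(sol$status, "infeasible")
  expect_identical(bf$status, "infeasible")
  expect_true(is.na(sol$objective))
})

test_that("a water limit admitting one plot picks the most profitable unit", {
  farm <- tiny_farm(22, n_rows = 2, n_cols = 2, n_freq = 2, n_seeds = 1)
  # allow slightly more water than the single cheapest productive option
  W <- farm$catalog$W
  active <- W[1, as.integer(t(farm$grid$cells))] # option 1 water per unit
  wl_total <- min(active) * 1.01
  spec <- model_spec("I", water_limit = wl_total / farm$econ$area)
  sol <- solve_farm_model(farm, spec)
  bf <- brute_force_solve(farm, spec)
  expect_same_optimum(sol, bf)
  if (sol$status == "optimal") expect_lte(sum(!sol$idle), 2)
})

test_that("decisions are uniform within decision units (shared partition)", {
  farm <- default_test_farm()
  part <- make_partition(18, 18, 4, "square")
  sol <- solve_farm_model(farm, model_spec("II", partition = part))
  expect_identical(sol$status, "optimal")
  mem <- partition_membership(part)
  opt <- as.integer(t(sol$option))
  expect_lte(length(unique(opt)), 4L)
  for (v in 1:4) expect_identical(length(unique(opt[mem == v])), 1L)
  audit <- audit_solution(sol, farm, model_spec("II", partition = part))
  expect_true(audit$ok)
})

test_that("the audit reproduces objectives and the water account", {
  farm <- default_test_farm()
  spec <- model_spec("I")
  sol <- solve_farm_model(farm, spec)
  audit <- audit_solution(sol, farm, spec)
  expect_true(audit$ok)
  expect_equal(audit$decomposition$objective, sol$objective,
    tolerance = 1e-6)
  # purchased water = applied / gamma + pre-irrigation, with gamma = 0.6
  dec <- sol$decomposition
  expect_equal(
    dec$water_purchased,
    dec$water_applied / 0.6 + farm$econ$pre_irrigation * farm$econ$area,
    tolerance = 1e-9
  )
  # water-limit slack is respected
  wrow <- audit$checks[audit$checks$check == "water_limit", ]
  expect_gte(wrow$slack, -1e-6 * abs(wrow$bound))
})

test_that("audit flags a corrupted solution", {
  farm <- tiny_farm(31, water_limit = 600)
  spec <- model_spec("I")
  sol <- solve_farm_model(farm, spec)
  if (sol$status == "optimal") {
    bad <- sol
    bad$objective <- sol$objective + 1000
    expect_error(audit_solution(bad, farm, spec), "objective_consistency")
    rep <- audit_solution(bad, farm, spec, error = FALSE)
    expect_false(rep$ok)
  }
})

test_that("profit is monotone along nested partitions", {
  farm <- default_test_farm()
  ladder <- c(1, 4, 36, 324)
  vals <- vapply(ladder, function(n) {
    solve_farm_model(farm,
      model_spec("II", partition = make_partition(18, 18, n, "square")))$objective
  }, 0)
  expect_true(all(diff(vals) >= -1e-6))
})

test_that("the nested model variants specialize exactly", {
  for (seed in c(2, 5)) {
    farm <- synthetic_farm(farm_recipe(seed = seed))
    singles <- make_partition(18, 18, 324, "square")
    expect_equal(
      solve_farm_model(farm, model_spec("I"))$objective,
      solve_farm_model(farm, model_spec("II", partition = singles))$objective,
      tolerance = 1e-9
    )
    P <- make_partition(18, 18, 9, "square")
    expect_equal(
      solve_farm_model(farm, model_spec("II", partition = P))$objective,
      solve_farm_model(farm,
        model_spec("III", seed_partition = P, irrigation_partition = P))$objective,
      tolerance = 1e-9
    )
  }
})

test_that("collapsed and explicit formulations agree", {
  farm <- default_test_farm()
  P <- make_partition(18, 18, 9, "square")
  spec <- model_spec("II", partition = P)
  a <- solve_farm_model(farm, spec, method = "collapse")
  b <- solve_farm_model(farm, spec, method = "explicit")
  expect_identical(a$solver$method, "collapse")
  expect_identical(b$solver$method, "explicit")
  expect_same_optimum(a, b)
  # small random instances too
  for (seed in 41:44) {
    farm2 <- tiny_farm(seed, n_rows = 2, n_cols = 2, water_limit = 900)
    p2 <- make_partition(2, 2, 2, "row")
    s2 <- model_spec("II", partition = p2)
    expect_same_optimum(
      solve_farm_model(farm2, s2, method = "collapse"),
      solve_farm_model(farm2, s2, method = "explicit")
    )
  }
})

test_that("independent partitions match enumeration on small grids", {
  for (seed in 51:56) {
    farm <- tiny_farm(seed, n_rows = 2, n_cols = 2, n_freq = 3, n_seeds = 2,
      water_limit = if (seed %% 2) 800 else Inf)
    spec <- model_spec("III",
      seed_partition = make_partition(2, 2, 2, "row"),
      irrigation_partition = make_partition(2, 2, 2, "column")
    )
    sol <- solve_farm_model(farm, spec)
    bf <- brute_force_solve(farm, spec)
    expect_same_optimum(sol, bf)
    if (sol$status == "optimal") {
      expect_true(audit_solution(sol, farm, spec)$ok)
    }
  }
})

test_that("the enumeration oracle refuses oversized instances", {
  farm <- default_test_farm()
  expect_error(brute_force_solve(farm, model_spec("I"), cap = 1e6), "cap")
})
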