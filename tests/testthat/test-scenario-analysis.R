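test_that("scale regression recovers an exact law and matches lm", {
  d <- data.frame(n_units = c(1, 2, 4, 8, 16), shape = "row",
    profit = 5 + 2 * log(c(1, 2, 4, 8, 16)))
  expect_message(fit <- suppressWarnings(fit_scale_regression(d)), "single shape group")
  expect_equal(fit$beta0, 5, tolerance = 1e-9)
  expect_equal(fit$beta1, 2, tolerance = 1e-9)
  expect_true(is.na(fit$beta2))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # independent closed-form OLS oracle (normal equations) on random data
  set.seed(404)
  for (rep in 1:5) {
    d <- data.frame(
      n_units = rep(c(1, 2, 3, 4, 6, 9, 18, 36), 2),
      shape = sample(c("square", "row"), 16, replace = TRUE)
    )
    d$shape[1] <- "square"; d$shape[2] <- "row"
    d$profit <- rnorm(16, 1000, 300)
    X <- cbind(1, log(d$n_units), log(d$n_units) * (d$shape == "square"))
    beta <- solve(t(X) %*% X, t(X) %*% d$profit)
    fit <- fit_scale_regression(d)
    expect_equal(c(fit$beta0, fit$beta1, fit$beta2), as.numeric(beta),
      tolerance = 1e-8)
    resid <- d$profit - X %*% beta
    expect_equal(fit$sigma, sqrt(sum(resid^2) / (16 - 3)), tolerance = 1e-8)
    sst <- sum((d$profit - mean(d$profit))^2)
    expect_equal(fit$r_squared, 1 - sum(resid^2) / sst, tolerance = 1e-8)
    expect_equal(predict(fit, d), as.numeric(X %*% beta), tolerance = 1e-8)
  }
  expect_error(fit_scale_regression(data.frame(n_units = 1:3, shape = "row",
    profit = 1:3)), "at least 4")
})

test_that("scenario table reports gain ratios against the uniform baseline", {
  farm <- default_test_farm()
  sub <- scale_scenarios()[c(1, 6, 11, 14, 16), ]
  tab <- run_scenario_table(farm, sub)
  expect_identical(names(tab),
    c("scenario", "n_units", "shape", "net_profit", "gain_ratio"))
  expect_equal(tab$gain_ratio[1], 1)
  expect_equal(tab$gain_ratio, tab$net_profit / tab$net_profit[1])
  # nested square ladder: 1 -> 4 -> 9 -> 36 -> 324 is nondecreasing
  expect_true(all(diff(tab$net_profit) >= -1e-6))
})

test_that("uniform irrigation never beats sharing the seed partition", {
  farm <- default_test_farm()
  sub <- scale_scenarios()[c(1, 6), ]
  tab <- run_pattern_table(farm, sub)
  expect_true(all(tab$pattern3 <= tab$model2 + 1e-6))
  expect_true(all(tab$rgi >= 1 - 1e-9))
  # degenerate single-unit farm: every pattern collapses to one decision
  tiny <- tiny_farm(61, n_rows = 1, n_cols = 1)
  t1 <- run_pattern_table(tiny, data.frame(scenario = 1, n_units = 1, shape = "square"))
  expect_equal(t1$pattern1, t1$pattern3, tolerance = 1e-9)
  expect_equal(t1$rgi, 1, tolerance = 1e-9)
})

test_that("optimal profit responds monotonically to single parameters", {
  farm <- default_test_farm()
  sweep <- one_at_a_time_sensitivity(farm,
    params = list(
      corn_price = c(100, 200),
      water_price = c(0.05, 0.4),
      gamma = c(0.45, 0.75)
    ),
    n_points = 4
  )
  by_par <- split(sweep, sweep$parameter)
  up <- function(d) all(diff(d$net_profit[order(d$value)]) >= -1e-6)
  down <- function(d) all(diff(d$net_profit[order(d$value)]) <= 1e-6)
  expect_true(up(by_par$corn_price))
  expect_true(down(by_par$water_price))
  expect_true(up(by_par$gamma))
  # a degenerate range evaluates to the base optimum
  flat <- one_at_a_time_sensitivity(farm, params = list(corn_price = c(141, 141)))
  expect_equal(flat$net_profit, attr(flat, "base_profit"))
  expect_error(
    one_at_a_time_sensitivity(farm, params = list(nonsense = c(0, 1))),
    "unknown sensitivity parameter"
  )
})

test_that("fixed-decision sensitivity never beats re-optimization", {
  farm <- default_test_farm()
  prm <- list(water_price = c(0.05, 0.3))
  reopt <- one_at_a_time_sensitivity(farm, params = prm, n_points = 3)
  fixed <- one_at_a_time_sensitivity(farm, params = prm, n_points = 3,
    reoptimize = FALSE)
  expect_true(all(fixed$net_profit <= reopt$net_profit + 1e-6))
})

test_that("break-even prices are roots of the optimal-value function", {
  # hand-built single-unit farm: profit linear in corn price
  farm <- tiny_farm(71, n_rows = 1, n_cols = 1, n_freq = 2, n_seeds = 1)
  cat <- farm$catalog
  j <- farm$grid$cells[1, 1]
  E <- farm$grid$unit_area
  # closed form: the only productive option breaks even when
  # Y E P + Y E a(1-b)Rb/(1-a) - Cm E - Cf E - W Cw/g - Co A = 0
  econ <- farm$econ
  resid_coef <- econ$alpha * (1 - econ$beta) * econ$residue_price / (1 - econ$alpha)
  num <- cat$C_m[1, j] * E + cat$C_f[1, j] * E +
    cat$W[1, j] * econ$water_price / econ$gamma +
    econ$overhead_cost * econ$area - cat$Y[1, j] * E * resid_coef
  p_star <- num / (cat$Y[1, j] * E)
  expect_gt(p_star, 0)
  got <- breakeven_price(farm, "corn_price", bracket = c(0.1, 2 * p_star + 10),
    tol = 1e-4)
  expect_equal(got, p_star, tolerance = 1e-2)
  # invariant to the starting bracket, as long as it contains the root
  got2 <- breakeven_price(farm, "corn_price",
    bracket = c(p_star / 3, p_star * 1.3), tol = 1e-4)
  expect_equal(got2, p_star, tolerance = 1e-2)

  # a zero-yield catalogue earns nothing at any corn price: the optimum
  # stays at the all-fallow overhead loss and never crosses zero
  fallow <- tiny_farm(72, n_rows = 2, n_cols = 2)
  fallow$catalog$Y[] <- 0
  expect_error(breakeven_price(fallow, "corn_price"), "no break-even")
})

test_that("the profit region is monotone in both prices", {
  farm <- default_test_farm()
  reg <- profit_region(farm,
    corn_grid = c(60, 90, 120, 160, 200),
    water_grid = c(0.02, 0.1, 0.25, 0.5)
  )
  # nondecreasing in corn price down each column
  expect_true(all(apply(reg$profit, 2, function(x) all(diff(x) >= -1e-6))))
  # nonincreasing in water price along each row
  expect_true(all(apply(reg$profit, 1, function(x) all(diff(x) <= 1e-6))))
  # at a vanishing corn price the farm cannot be profitable
  reg0 <- profit_region(farm, corn_grid = 0, water_grid = c(0.02, 0.25))
  expect_true(all(reg0$profit < 0))
  # boundary consistency: the trigger price separates the base-water column
  trigger <- breakeven_price(farm, "corn_price", tol = 0.05)
  regb <- profit_region(farm,
    corn_grid = c(trigger - 5, trigger + 5),
    water_grid = farm$econ$water_price
  )
  expect_lt(regb$profit[1, 1], 0)
  expect_gt(regb$profit[2, 1], 0)
})
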