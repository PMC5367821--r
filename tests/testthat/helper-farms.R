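# Fixture builders ----------------------------------------------------------

# Small random farm with arbitrary (valid) agronomic tables, for oracle
# equivalence tests. Tables are random on purpose: the solver contract
# holds for any catalogue, not only calibrated ones.
tiny_farm <- function(seed, n_rows = 2, n_cols = 2, n_classes = 2,
                      n_freq = 3, n_seeds = 2, water_limit = Inf,
                      irrigation_budget = Inf, operating_budget = Inf,
                      min_yield = 0) {
  set.seed(seed)
  stopifnot(n_freq >= 2)
  intervals <- c(7 * seq_len(n_freq - 1), NA)
  frequencies <- data.frame(
    id = seq_len(n_freq),
    label = c(paste0("f", seq_len(n_freq - 1)), "never"),
    interval_days = intervals,
    events = c(sort(sample(1:12, n_freq - 1), decreasing = TRUE), 0L)
  )
  seeds <- data.frame(
    id = seq_len(n_seeds),
    name = paste0("seed", seq_len(n_seeds)),
    class = "test",
    max_yield = runif(n_seeds, 8, 19),
    sensitivity = runif(n_seeds, 0.4, 1.6),
    survival_water = 0
  )
  soils <- soil_classes(n_classes)
  I <- n_freq * n_seeds
  J <- n_classes
  fallow <- which(rep(frequencies$events, each = n_seeds) == 0L)
  rmat <- function(lo, hi) {
    m <- matrix(runif(I * J, lo, hi), I, J)
    m[fallow, ] <- 0
    m
  }
  catalog <- management_catalog(
    frequencies, seeds, soils,
    Y = rmat(0, 19), W = rmat(0, 600), C_f = rmat(10, 400), C_m = rmat(0, 1400)
  )
  cells <- matrix(sample(seq_len(J), n_rows * n_cols, replace = TRUE),
    n_rows, n_cols)
  cells[1] <- J # every class id reachable
  grid <- soil_grid(cells, classes = soils)
  econ <- default_economics(
    area = n_units(grid) * grid$unit_area,
    water_limit = water_limit,
    irrigation_budget = irrigation_budget,
    operating_budget = operating_budget,
    min_yield = min_yield,
    pre_irrigation = 0
  )
  farm_from_parts(grid, catalog, econ)
}

# The default calibrated synthetic farm, built once per test run.
default_test_farm <- local({
  farm <- NULL
  function() {
    if (is.null(farm)) farm <<- synthetic_farm(farm_recipe(seed = 1))
    farm
  }
})

expect_same_optimum <- function(a, b, tol = 1e-9) {
  expect_identical(a$status, b$status)
  if (a$status == "optimal") {
    expect_equal(a$objective, b$objective, tolerance = tol)
  }
}
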