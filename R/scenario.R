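# Scenario, sensitivity, and scale analyses ---------------------------------

#' Gain ratio of scenario profits over a baseline
#'
#' The gain ratio of a management-scale scenario is its net profit divided
#' by the profit of the whole-farm uniform baseline (scenario 1).
#'
#' @param net_profit numeric vector of scenario profits.
#' @param baseline baseline profit; defaults to the first element.
#' @return numeric vector of ratios (the baseline maps to 1).
#' @export
gain_ratio <- function(net_profit, baseline = net_profit[1]) {
  net_profit / baseline
}

#' Relative gain for customized irrigation (RGI)
#'
#' For a fixed seed-precision scenario, the best profit attainable with
#' per-row (Pattern 1), per-column (Pattern 2) or fully shared-partition
#' (Model II) irrigation, divided by the profit under whole-farm uniform
#' irrigation (Pattern 3).
#'
#' @param pattern1,pattern2,pattern3 profits under the three irrigation
#'   patterns.
#' @param model2 profit when irrigation shares the seed partition.
#' @return numeric vector of RGI values.
#' @export
relative_gain_irrigation <- function(pattern1, pattern2, model2, pattern3) {
  pmax(pattern1, pattern2, model2) / pattern3
}

#' Profit across the management-scale scenario ladder
#'
#' Solves the shared-partition model (Model II) for each scenario of the
#' ladder and reports net profit and gain ratio against scenario 1.
#' Scenarios that fail (e.g. an untileable shape) propagate as `NA` with a
#' warning, without aborting the rest of the table.
#'
#' @param farm a `farm` object.
#' @param scenarios data.frame with columns `scenario`, `n_units`, `shape`;
#'   defaults to [scale_scenarios()].
#' @param control a [solver_control()].
#' @return data.frame with columns `scenario`, `n_units`, `shape`,
#'   `net_profit`, `gain_ratio`.
#' @export
run_scenario_table <- function(farm, scenarios = scale_scenarios(),
                               control = solver_control()) {
  M <- nrow(farm$grid$cells)
  N <- ncol(farm$grid$cells)
  profit <- rep(NA_real_, nrow(scenarios))
  for (k in seq_len(nrow(scenarios))) {
    profit[k] <- tryCatch({
      part <- make_partition(M, N, scenarios$n_units[k], scenarios$shape[k])
      sol <- solve_farm_model(farm, model_spec("II", partition = part),
        control = control)
      if (sol$status != "optimal") NA_real_ else sol$objective
    }, error = function(e) {
      warning("scenario ", scenarios$scenario[k], " failed: ",
        conditionMessage(e), call. = FALSE)
      NA_real_
    })
  }
  data.frame(
    scenario = scenarios$scenario,
    n_units = scenarios$n_units,
    shape = scenarios$shape,
    net_profit = profit,
    gain_ratio = gain_ratio(profit),
    stringsAsFactors = FALSE
  )
}

#' Profit under constrained irrigation patterns
#'
#' For each seed-precision scenario, solves the independent-partition model
#' (Model III) under three fixed irrigation patterns - per-row strips
#' (Pattern 1), per-column strips (Pattern 2), and whole-farm uniform
#' irrigation (Pattern 3) - plus the shared-partition Model II, and
#' computes the relative gain for customized irrigation.
#'
#' @inheritParams run_scenario_table
#' @return data.frame with columns `scenario`, `n_units`, `shape`,
#'   `pattern1`, `pattern2`, `pattern3`, `model2`, `rgi`.
#' @export
run_pattern_table <- function(farm, scenarios = scale_scenarios(),
                              control = solver_control()) {
  M <- nrow(farm$grid$cells)
  N <- ncol(farm$grid$cells)
  irr <- list(
    pattern1 = make_partition(M, N, M, "row"),
    pattern2 = make_partition(M, N, N, "column"),
    pattern3 = make_partition(M, N, 1, "square")
  )
  out <- data.frame(
    scenario = scenarios$scenario, n_units = scenarios$n_units,
    shape = scenarios$shape, pattern1 = NA_real_, pattern2 = NA_real_,
    pattern3 = NA_real_, model2 = NA_real_, rgi = NA_real_,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(scenarios))) {
    res <- tryCatch({
      seedp <- make_partition(M, N, scenarios$n_units[k], scenarios$shape[k])
      p <- vapply(irr, function(ip) {
        sol <- solve_farm_model(
          farm,
          model_spec("III", seed_partition = seedp, irrigation_partition = ip),
          control = control
        )
        if (sol$status != "optimal") NA_real_ else sol$objective
      }, 0)
      m2 <- solve_farm_model(farm, model_spec("II", partition = seedp),
        control = control)
      c(p, model2 = if (m2$status != "optimal") NA_real_ else m2$objective)
    }, error = function(e) {
      warning("scenario ", scenarios$scenario[k], " failed: ",
        conditionMessage(e), call. = FALSE)
      rep(NA_real_, 4)
    })
    out[k, c("pattern1", "pattern2", "pattern3", "model2")] <- res
  }
  out$rgi <- relative_gain_irrigation(out$pattern1, out$pattern2, out$model2,
    out$pattern3)
  out
}

#' Log-scale regression of profit against management granularity
#'
#' Fits, by ordinary least squares, the model
#' \deqn{P = \beta_0 + \beta_1 \ln(n) + \beta_2 \ln(n) I(shape = square) + \varepsilon,}
#' where `n` is the number of decision units: `beta0` is the whole-farm
#' baseline profit, `beta1` the profit increment per unit of `ln(n)`, and
#' `beta1 + beta2` that increment for square decision units. The residual
#' standard error uses `n_obs - 3` degrees of freedom.
#'
#' When every observation falls in a single shape group the square
#' indicator column is collinear with `ln(n)` and is dropped with a
#' message.
#'
#' @param results data.frame with columns `n_units`, `shape`, and a profit
#'   column (`net_profit` or `profit`).
#' @return an object of class `scale_regression`: list with `beta0`,
#'   `beta1`, `beta2` (NA when dropped), `sigma`, `r_squared`, `fitted`,
#'   `data`.
#' @export
fit_scale_regression <- function(results) {
  pcol <- intersect(c("net_profit", "profit"), names(results))[1]
  if (is.na(pcol)) stop("no `net_profit` or `profit` column", call. = FALSE)
  stopifnot(all(c("n_units", "shape") %in% names(results)))
  d <- data.frame(
    profit = results[[pcol]],
    ln = log(results$n_units),
    sq = log(results$n_units) * as.numeric(results$shape == "square")
  )
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 4L) stop("need at least 4 complete observations", call. = FALSE)
  drop_sq <- isTRUE(all.equal(d$sq, d$ln)) || all(d$sq == 0)
  fit <- if (drop_sq) {
    message("single shape group: dropping the square-indicator term")
    lm(profit ~ ln, data = d)
  } else {
    lm(profit ~ ln + sq, data = d)
  }
  cf <- coef(fit)
  if (anyNA(cf)) stop("singular regression design (rank-deficient)", call. = FALSE)
  sm <- summary(fit)
  structure(
    list(
      beta0 = unname(cf[1]),
      beta1 = unname(cf[2]),
      beta2 = if (drop_sq) NA_real_ else unname(cf[3]),
      sigma = sm$sigma,
      r_squared = sm$r.squared,
      fitted = unname(stats::fitted(fit)),
      data = d
    ),
    class = "scale_regression"
  )
}

#' @export
print.scale_regression <- function(x, ...) {
  cat("Profit ~ ln(decision units) regression\n")
  cat(sprintf("  beta0 (baseline)        %10.2f $\n", x$beta0))
  cat(sprintf("  beta1 (per ln n)        %10.2f $\n", x$beta1))
  if (!is.na(x$beta2)) {
    cat(sprintf("  beta2 (square premium)  %10.2f $\n", x$beta2))
  }
  cat(sprintf("  sigma                   %10.1f $   R-squared %.4f\n",
    x$sigma, x$r_squared))
  invisible(x)
}

#' @export
predict.scale_regression <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  ln <- log(newdata$n_units)
  sq <- ln * as.numeric(newdata$shape == "square")
  b2 <- if (is.na(object$beta2)) 0 else object$beta2
  object$beta0 + object$beta1 * ln + b2 * sq
}

# Return a copy of the farm with one swept parameter applied. Economic
# scalars are replaced; "operating_cost" rescales the whole C_m table
# around its current peak rate so the fallow zeros are preserved.
apply_sweep_param <- function(farm, name, value) {
  econ_fields <- c(
    "corn_price", "water_price", "overhead_cost", "gamma",
    "water_limit", "pre_irrigation", "residue_price", "alpha", "beta"
  )
  if (name %in% econ_fields) {
    farm$econ[[name]] <- value
    validate_economic_params(farm$econ)
  } else if (name == "operating_cost") {
    base <- max(farm$catalog$C_m)
    if (base <= 0) stop("catalogue has no operating costs to rescale", call. = FALSE)
    farm$catalog$C_m <- farm$catalog$C_m * (value / base)
  } else {
    stop("unknown sensitivity parameter `", name, "`", call. = FALSE)
  }
  farm
}

default_sweep_ranges <- function(farm) {
  base_cm <- max(farm$catalog$C_m)
  list(
    corn_price = c(71.65, 271.26), # historical grain-price range
    water_price = c(0.073, 0.89), # district average to drought-auction peak
    operating_cost = base_cm * c(0.75, 1.25),
    overhead_cost = farm$econ$overhead_cost * c(0.75, 1.25),
    gamma = farm$econ$gamma * c(0.75, 1.25),
    water_limit = farm$econ$water_limit * c(0.75, 1.25)
  )
}

#' One-at-a-time sensitivity of the optimal profit
#'
#' Re-solves the model along a grid of values for each parameter in turn,
#' holding all others at base levels. By default the plan is re-optimized
#' at every grid point; with `reoptimize = FALSE` the base-case decisions
#' are held fixed and only re-priced.
#'
#' @param farm a `farm` object.
#' @param spec a [model_spec()]; the basic per-land-unit model by default.
#' @param params named list of length-2 ranges `c(low, high)`. The default
#'   sweeps corn price and water price over historical ranges and the
#'   operating / overhead / efficiency / water-limit parameters over
#'   plus or minus 25 percent.
#' @param n_points grid points per parameter (endpoints included).
#' @param reoptimize re-solve at each point (default) or re-price the base
#'   plan.
#' @param control a [solver_control()].
#' @return data.frame of class `sensitivity_table` with columns
#'   `parameter`, `value`, `net_profit`; the base-case profit is stored in
#'   `attr(, "base_profit")`.
#' @export
one_at_a_time_sensitivity <- function(farm, spec = model_spec("I"),
                                      params = NULL, n_points = 5,
                                      reoptimize = TRUE,
                                      control = solver_control()) {
  if (is.null(params)) params <- default_sweep_ranges(farm)
  stopifnot(n_points >= 2 || all(vapply(params, function(p) p[1] == p[2], TRUE)))
  base_sol <- solve_farm_model(farm, spec, control = control)
  if (base_sol$status != "optimal") stop("base case is infeasible", call. = FALSE)
  rows <- list()
  for (name in names(params)) {
    rng <- params[[name]]
    if (length(rng) != 2L) stop("range for `", name, "` must be c(low, high)", call. = FALSE)
    grid <- if (rng[1] == rng[2]) rng[1] else seq(rng[1], rng[2], length.out = n_points)
    for (v in grid) {
      fm <- apply_sweep_param(farm, name, v)
      profit <- if (reoptimize) {
        sol <- solve_farm_model(fm, spec, control = control)
        if (sol$status != "optimal") NA_real_ else sol$objective
      } else {
        compute_decomposition(
          fm,
          as.integer(t(base_sol$frequency)),
          as.integer(t(base_sol$seed))
        )$objective
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = name, value = v, net_profit = profit,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "base_profit") <- base_sol$objective
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' Tornado summary of a sensitivity sweep
#'
#' @param sweep a table from [one_at_a_time_sensitivity()].
#' @return data.frame with one row per parameter: profit at the low and
#'   high end of its sweep and the absolute profit swing, sorted by swing.
#' @export
sensitivity_summary <- function(sweep) {
  sp <- split(sweep, sweep$parameter)
  out <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$value), ]
    data.frame(
      parameter = d$parameter[1],
      profit_low = d$net_profit[1],
      profit_high = d$net_profit[nrow(d)],
      swing = max(d$net_profit, na.rm = TRUE) - min(d$net_profit, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  out
}

#' Break-even price for the optimal plan
#'
#' Finds the price at which the optimal annual net profit crosses zero:
#' the *trigger* corn price below which growing cannot cover farm costs,
#' or the *termination* water price above which farming becomes
#' unprofitable. The optimal-value function is monotone in either price,
#' so the root is isolated by bisection.
#'
#' @param farm a `farm` object.
#' @param which `"corn_price"` or `"water_price"`.
#' @param spec a [model_spec()].
#' @param bracket length-2 search interval; defaults to `c(1, 400)` $/t
#'   for corn and `c(0.001, 2)` $/m3 for water.
#' @param tol absolute price tolerance of the returned threshold.
#' @param control a [solver_control()].
#' @return the break-even price (a scalar).
#' @export
breakeven_price <- function(farm, which = c("corn_price", "water_price"),
                            spec = model_spec("I"), bracket = NULL,
                            tol = 0.01, control = solver_control()) {
  which <- match.arg(which)
  if (is.null(bracket)) {
    bracket <- if (which == "corn_price") c(1, 400) else c(0.001, 2)
  }
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  profit_at <- function(p) {
    sol <- solve_farm_model(apply_sweep_param(farm, which, p), spec,
      control = control)
    if (sol$status != "optimal") stop("model infeasible at ", which, " = ", p, call. = FALSE)
    sol$objective
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- profit_at(lo); f_hi <- profit_at(hi)
  if (sign(f_lo) == sign(f_hi)) {
    stop("no break-even in range [", lo, ", ", hi, "]: profit is ",
      if (f_lo > 0) "positive" else "non-positive", " throughout", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- profit_at(mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid; f_hi <- f_mid
    }
  }
  (lo + hi) / 2
}

#' Profit over a corn-price x water-price grid
#'
#' Solves the model at every combination of the two prices, mapping the
#' profitable and non-profitable regions of the price plane. The
#' profitable set is monotone: up-closed in corn price and down-closed in
#' water price.
#'
#' @param farm a `farm` object.
#' @param corn_grid,water_grid ascending price grids ($/t, $/m3).
#' @param spec a [model_spec()].
#' @param control a [solver_control()].
#' @return an object of class `profit_region`: list with `corn_price`,
#'   `water_price`, `profit` (matrix, corn in rows), `profitable`
#'   (logical matrix).
#' @export
profit_region <- function(farm, corn_grid, water_grid,
                          spec = model_spec("I"), control = solver_control()) {
  stopifnot(!is.unsorted(corn_grid), !is.unsorted(water_grid))
  prof <- matrix(NA_real_, length(corn_grid), length(water_grid),
    dimnames = list(corn_grid, water_grid))
  for (a in seq_along(corn_grid)) {
    fm_p <- apply_sweep_param(farm, "corn_price", corn_grid[a])
    for (bb in seq_along(water_grid)) {
      fm <- apply_sweep_param(fm_p, "water_price", water_grid[bb])
      sol <- solve_farm_model(fm, spec, control = control)
      prof[a, bb] <- if (sol$status != "optimal") NA_real_ else sol$objective
    }
  }
  structure(
    list(
      corn_price = corn_grid, water_price = water_grid,
      profit = prof, profitable = prof > 0
    ),
    class = "profit_region"
  )
}

#' @export
print.profit_region <- function(x, ...) {
  cat(sprintf(
    "Profit region over %d corn prices x %d water prices: %.0f%% profitable\n",
    length(x$corn_price), length(x$water_price),
    100 * mean(x$profitable, na.rm = TRUE)
  ))
  invisible(x)
}
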