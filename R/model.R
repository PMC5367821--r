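# Model construction, solving, auditing -------------------------------------

#' Specify a planning-model variant
#'
#' Three nested variants of the farm MILP:
#' * **I** - every land unit decides independently (both partitions are
#'   singletons); the upper bound on attainable profit.
#' * **II** - seed and irrigation decisions are uniform within one shared
#'   decision-unit partition.
#' * **III** - seed and irrigation use independent partitions (e.g. seed
#'   chosen per block but irrigation switched per row).
#'
#' Budget / yield / water bounds default to the values in the farm's
#' economic parameters; infinite budgets (and a zero yield floor) simply
#' drop the corresponding constraint.
#'
#' @param variant `"I"`, `"II"`, or `"III"`.
#' @param partition decision-unit partition (variant II).
#' @param seed_partition,irrigation_partition partitions for variant III.
#' @param irrigation_budget,operating_budget,min_yield,water_limit optional
#'   overrides of the corresponding [economic_params()] fields.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(variant = c("I", "II", "III"),
                       partition = NULL,
                       seed_partition = NULL,
                       irrigation_partition = NULL,
                       irrigation_budget = NULL,
                       operating_budget = NULL,
                       min_yield = NULL,
                       water_limit = NULL) {
  variant <- match.arg(variant)
  if (variant == "II") {
    if (is.null(partition)) stop("variant II needs a `partition`", call. = FALSE)
    seed_partition <- partition
    irrigation_partition <- partition
  } else if (variant == "III") {
    if (is.null(seed_partition) || is.null(irrigation_partition)) {
      stop("variant III needs `seed_partition` and `irrigation_partition`", call. = FALSE)
    }
  } else {
    seed_partition <- NULL # singletons, resolved against the grid at solve time
    irrigation_partition <- NULL
  }
  structure(
    list(
      variant = variant,
      seed_partition = seed_partition,
      irrigation_partition = irrigation_partition,
      irrigation_budget = irrigation_budget,
      operating_budget = operating_budget,
      min_yield = min_yield,
      water_limit = water_limit
    ),
    class = "model_spec"
  )
}

singleton_partition <- function(n_rows, n_cols) {
  make_partition(n_rows, n_cols, n_rows * n_cols, "square")
}

resolve_partitions <- function(farm, spec) {
  M <- nrow(farm$grid$cells)
  N <- ncol(farm$grid$cells)
  if (spec$variant == "I") {
    p <- singleton_partition(M, N)
    return(list(seed = p, irrigation = p))
  }
  for (p in list(spec$seed_partition, spec$irrigation_partition)) {
    if (p$n_rows != M || p$n_cols != N) {
      stop("partition grid (", p$n_rows, " x ", p$n_cols,
        ") does not match the farm grid (", M, " x ", N, ")", call. = FALSE)
    }
  }
  list(seed = spec$seed_partition, irrigation = spec$irrigation_partition)
}

model_bounds <- function(farm, spec) {
  econ <- farm$econ
  list(
    irrigation_budget = spec$irrigation_budget %||% econ$irrigation_budget,
    operating_budget = spec$operating_budget %||% econ$operating_budget,
    min_yield = spec$min_yield %||% econ$min_yield,
    water_limit = spec$water_limit %||% econ$water_limit
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Aggregate the farm + spec into the solver's cell-level arrays. Cells are
# the common refinement of the two partitions; per-cell coefficients sum
# unit-level coefficients over the member land units.
build_problem <- function(farm, spec) {
  grid <- farm$grid
  catalog <- farm$catalog
  econ <- farm$econ
  E <- grid$unit_area
  U <- n_units(grid)
  A <- econ$area

  if (abs(A - U * E) > 0.02 * A) {
    warning(sprintf(
      "configured farm area (%.2f ha) differs from grid area (%.2f ha) by more than 2%%",
      A, U * E
    ), call. = FALSE)
  }

  parts <- resolve_partitions(farm, spec)
  mem_s <- partition_membership(parts$seed)
  mem_i <- partition_membership(parts$irrigation)
  merged <- identical(mem_s, mem_i)

  key <- (mem_i - 1L) * max(mem_s) + mem_s
  cell_of_unit <- match(key, sort(unique(key)))
  C <- max(cell_of_unit)
  irr_block <- integer(C)
  seed_block <- integer(C)
  irr_block[cell_of_unit] <- mem_i
  seed_block[cell_of_unit] <- mem_s

  counts <- rowsum(soil_indicator(grid), cell_of_unit) # C x J

  R <- nrow(catalog$frequencies)
  S <- nrow(catalog$seeds)
  netIJ <- profit_matrix(catalog, econ, E)
  PC <- counts %*% t(netIJ) # C x I

  bounds <- model_bounds(farm, spec)
  usage <- list()
  b <- numeric(0)
  cname <- character(0)
  add_constraint <- function(tabIJ, rhs, name) {
    usage[[length(usage) + 1L]] <<- counts %*% t(tabIJ)
    b[length(b) + 1L] <<- rhs
    cname[length(cname) + 1L] <<- name
  }
  if (is.finite(bounds$irrigation_budget)) {
    add_constraint(
      catalog$C_f * E + catalog$W * econ$water_price / econ$gamma,
      bounds$irrigation_budget, "irrigation_budget"
    )
  }
  if (is.finite(bounds$operating_budget)) {
    add_constraint(catalog$C_m * E, bounds$operating_budget, "operating_budget")
  }
  if (bounds$min_yield > 0) {
    add_constraint(-(catalog$Y * E), -bounds$min_yield, "min_yield")
  }
  if (is.finite(bounds$water_limit)) {
    add_constraint(
      catalog$W / econ$gamma,
      bounds$water_limit * A - econ$pre_irrigation * A, "water_limit"
    )
  }

  list(
    C = C, R = R, S = S,
    cell_of_unit = cell_of_unit, irr_block = irr_block, seed_block = seed_block,
    merged = merged, PC = PC, usage = usage, b = b, constraint_names = cname,
    parts = parts, bounds = bounds
  )
}

# Reshape a C x I matrix (columns i = (r-1)*S + s) into a C x R x S array.
to_rs_array <- function(M, R, S) {
  aperm(array(M, dim = c(nrow(M), S, R)), c(1, 3, 2))
}

#' Objective coefficients of the planning MILP
#'
#' Returns the per-land-unit, per-option net-profit coefficients of the
#' objective (the coefficient of the binary assignment of option `i` to
#' unit `u` is the unit's net profit under that option on its soil) plus
#' the decision-independent constant `-overhead * area`.
#'
#' @param farm a `farm` object.
#' @return list with `coefficients` (a `U x I` matrix, units row-major) and
#'   `constant` (a scalar).
#' @export
objective_coefficients <- function(farm) {
  netIJ <- profit_matrix(farm$catalog, farm$econ, farm$grid$unit_area)
  j <- unit_soil(farm$grid)
  list(
    coefficients = t(netIJ[, j, drop = FALSE]),
    constant = -farm$econ$overhead_cost * farm$econ$area
  )
}

#' Solve the farm planning model exactly
#'
#' Builds the MILP for the given variant and solves it with the package's
#' exact branch-and-bound solver. Two internal formulations are available:
#' `"collapse"` merges the per-land-unit variables of each decision unit
#' into one multiple-choice variable (possible when seed and irrigation
#' share a partition), while `"explicit"` keeps separate frequency and
#' seed block variables and enforces their consistency during the search.
#' Both are exact and must agree; `"auto"` picks whichever fits the spec.
#'
#' @param farm a `farm` object.
#' @param spec a [model_spec()].
#' @param method `"auto"`, `"collapse"`, or `"explicit"`.
#' @param control a [solver_control()].
#' @return an object of class `farm_solution`; see Details.
#' @details The solution carries the per-unit frequency/seed/option
#'   assignment (matrices in grid shape), the audited objective
#'   decomposition, the water account, and solver statistics. `status` is
#'   `"optimal"` or `"infeasible"`; for an infeasible model the objective
#'   is `NA`.
#' @export
solve_farm_model <- function(farm, spec = model_spec("I"),
                             method = c("auto", "collapse", "explicit"),
                             control = solver_control()) {
  method <- match.arg(method)
  prob <- build_problem(farm, spec)
  if (method == "collapse" && !prob$merged) {
    stop("`collapse` needs identical seed and irrigation partitions", call. = FALSE)
  }
  use_merged <- prob$merged && method != "explicit"

  if (use_merged) {
    res <- bb_mckp(prob$PC, prob$usage, prob$b, control)
    if (res$status != "optimal") {
      return(new_farm_solution(farm, spec, prob, NULL, NULL, res, "collapse"))
    }
    opt_cell <- res$choice
    rs <- option_rs(opt_cell, prob$R, prob$S)
    r_unit <- rs$r[prob$cell_of_unit]
    s_unit <- rs$s[prob$cell_of_unit]
  } else {
    P3 <- to_rs_array(prob$PC, prob$R, prob$S)
    U3 <- lapply(prob$usage, to_rs_array, R = prob$R, S = prob$S)
    res <- bb_two_sided(P3, U3, prob$b, prob$irr_block, prob$seed_block, control)
    if (res$status != "optimal") {
      return(new_farm_solution(farm, spec, prob, NULL, NULL, res, "explicit"))
    }
    r_cell <- res$r_choice[prob$irr_block]
    s_cell <- res$s_choice[prob$seed_block]
    r_unit <- r_cell[prob$cell_of_unit]
    s_unit <- s_cell[prob$cell_of_unit]
  }
  new_farm_solution(farm, spec, prob, r_unit, s_unit, res,
    if (use_merged) "collapse" else "explicit")
}

new_farm_solution <- function(farm, spec, prob, r_unit, s_unit, res, method) {
  M <- nrow(farm$grid$cells)
  N <- ncol(farm$grid$cells)
  if (is.null(r_unit)) {
    return(structure(
      list(
        status = res$status, objective = NA_real_, frequency = NULL,
        seed = NULL, option = NULL, idle = NULL, decomposition = NULL,
        variant = spec$variant, bounds = prob$bounds,
        solver = list(method = method, nodes = res$nodes, bound = res$bound)
      ),
      class = "farm_solution"
    ))
  }
  dec <- compute_decomposition(farm, r_unit, s_unit)
  to_grid <- function(v) matrix(v, M, N, byrow = TRUE)
  fallow_r <- farm$catalog$frequencies$id[farm$catalog$frequencies$events == 0L]
  if (length(fallow_r) == 0L) fallow_r <- -1L
  structure(
    list(
      status = "optimal",
      objective = dec$objective,
      frequency = to_grid(r_unit),
      seed = to_grid(s_unit),
      option = to_grid(option_index(r_unit, s_unit,
        nrow(farm$catalog$frequencies), nrow(farm$catalog$seeds))),
      idle = to_grid(r_unit == fallow_r),
      decomposition = dec,
      variant = spec$variant,
      bounds = prob$bounds,
      solver = list(method = method, nodes = res$nodes, bound = res$bound)
    ),
    class = "farm_solution"
  )
}

# Recompute the full objective decomposition of an assignment (unit-level
# frequency and seed vectors, row-major order) from first principles.
compute_decomposition <- function(farm, r_unit, s_unit) {
  catalog <- farm$catalog
  econ <- farm$econ
  E <- farm$grid$unit_area
  R <- nrow(catalog$frequencies)
  S <- nrow(catalog$seeds)
  i_unit <- option_index(r_unit, s_unit, R, S)
  j_unit <- unit_soil(farm$grid)
  idx <- cbind(i_unit, j_unit)
  tabs <- profit_tables(catalog, econ, E)
  comp <- lapply(tabs, function(tt) sum(tt[idx]))
  water_applied <- sum(catalog$W[idx])
  overhead <- econ$overhead_cost * econ$area
  objective <- comp$revenue_grain + comp$revenue_residue -
    comp$cost_operating - comp$cost_water - comp$cost_irrigation_fixed -
    overhead
  c(comp, list(
    overhead = overhead,
    objective = objective,
    yield_total = sum(catalog$Y[idx] * E),
    water_applied = water_applied,
    water_purchased = water_applied / econ$gamma + econ$pre_irrigation * econ$area
  ))
}

#' @export
print.farm_solution <- function(x, ...) {
  cat(sprintf("Farm plan (Model %s, %s formulation): %s\n",
    x$variant, x$solver$method, x$status))
  if (x$status == "optimal") {
    cat(sprintf("  net profit            %12.2f $\n", x$objective))
    cat(sprintf("  total yield           %12.2f t\n", x$decomposition$yield_total))
    cat(sprintf("  water purchased       %12.0f m3\n", x$decomposition$water_purchased))
    cat(sprintf("  idle land units       %12d\n", sum(x$idle)))
    cat(sprintf("  B&B nodes             %12d\n", x$solver$nodes))
  }
  invisible(x)
}

#' Exhaustive-search oracle for the planning model
#'
#' Solves the same model as [solve_farm_model()] by enumerating every
#' admissible assignment (one option per decision cell, or every
#' frequency/seed block combination for independent partitions) and
#' keeping the best feasible one. Exponential and only meant to verify the
#' branch-and-bound solver on tiny instances; refuses to enumerate more
#' than `cap` assignments. Ties are broken by the lexicographically
#' smallest assignment.
#'
#' @param farm a `farm` object.
#' @param spec a [model_spec()].
#' @param cap maximum number of assignments to enumerate.
#' @return a `farm_solution`, exactly as [solve_farm_model()].
#' @export
brute_force_solve <- function(farm, spec = model_spec("I"), cap = 1e6) {
  prob <- build_problem(farm, spec)
  feas_tol <- 1e-7 * pmax(1, abs(prob$b))

  if (prob$merged) {
    I <- ncol(prob$PC)
    n_comb <- I^prob$C
    if (n_comb > cap) {
      stop("enumeration would need ", format(n_comb, big.mark = ","),
        " assignments (cap ", format(cap, big.mark = ","), ")", call. = FALSE)
    }
    G <- as.matrix(expand.grid(rep(list(seq_len(I)), prob$C)))
    val <- 0
    feas <- TRUE
    for (cc in seq_len(prob$C)) val <- val + prob$PC[cc, G[, cc]]
    for (k in seq_along(prob$usage)) {
      uk <- 0
      for (cc in seq_len(prob$C)) uk <- uk + prob$usage[[k]][cc, G[, cc]]
      feas <- feas & (uk <= prob$b[k] + feas_tol[k])
    }
    val[!feas] <- -Inf
    if (!any(is.finite(val))) {
      return(new_farm_solution(farm, spec, prob, NULL, NULL,
        list(status = "infeasible", nodes = length(val), bound = NA_real_), "enumeration"))
    }
    top <- which(val >= max(val) - 1e-9 * max(1, abs(max(val))))
    pick <- top[do.call(order, as.data.frame(G[top, , drop = FALSE]))[1L]]
    opt_cell <- as.integer(G[pick, ])
    rs <- option_rs(opt_cell, prob$R, prob$S)
    r_unit <- rs$r[prob$cell_of_unit]
    s_unit <- rs$s[prob$cell_of_unit]
    res <- list(status = "optimal", nodes = length(val), bound = max(val))
  } else {
    Q <- max(prob$irr_block)
    Pn <- max(prob$seed_block)
    n_comb <- prob$R^Q * prob$S^Pn
    if (n_comb > cap) {
      stop("enumeration would need ", format(n_comb, big.mark = ","),
        " assignments (cap ", format(cap, big.mark = ","), ")", call. = FALSE)
    }
    G <- as.matrix(expand.grid(c(
      rep(list(seq_len(prob$R)), Q),
      rep(list(seq_len(prob$S)), Pn)
    )))
    P3 <- to_rs_array(prob$PC, prob$R, prob$S)
    U3 <- lapply(prob$usage, to_rs_array, R = prob$R, S = prob$S)
    n <- nrow(G)
    val <- 0
    feas <- TRUE
    for (cc in seq_len(prob$C)) {
      idx <- cbind(rep.int(cc, n), G[, prob$irr_block[cc]], G[, Q + prob$seed_block[cc]])
      val <- val + P3[idx]
    }
    for (k in seq_along(U3)) {
      uk <- 0
      for (cc in seq_len(prob$C)) {
        idx <- cbind(rep.int(cc, n), G[, prob$irr_block[cc]], G[, Q + prob$seed_block[cc]])
        uk <- uk + U3[[k]][idx]
      }
      feas <- feas & (uk <= prob$b[k] + feas_tol[k])
    }
    val[!feas] <- -Inf
    if (!any(is.finite(val))) {
      return(new_farm_solution(farm, spec, prob, NULL, NULL,
        list(status = "infeasible", nodes = n, bound = NA_real_), "enumeration"))
    }
    top <- which(val >= max(val) - 1e-9 * max(1, abs(max(val))))
    pick <- top[do.call(order, as.data.frame(G[top, , drop = FALSE]))[1L]]
    r_cell <- as.integer(G[pick, seq_len(Q)])[prob$irr_block]
    s_cell <- as.integer(G[pick, Q + seq_len(Pn)])[prob$seed_block]
    r_unit <- r_cell[prob$cell_of_unit]
    s_unit <- s_cell[prob$cell_of_unit]
    res <- list(status = "optimal", nodes = n, bound = max(val))
  }
  new_farm_solution(farm, spec, prob, r_unit, s_unit, res, "enumeration")
}

#' Audit a solved plan
#'
#' Recomputes every objective component, the water account, and all
#' constraint left-hand sides directly from the per-unit assignment, then
#' checks them against the solver's reported objective and the model's
#' bounds. Uniformity of decisions within decision units and the
#' one-frequency / one-seed-per-unit conditions are verified as well.
#'
#' @param solution a `farm_solution` with status `"optimal"`.
#' @param farm,spec the inputs it was solved from.
#' @param tol relative tolerance for flagging violations.
#' @param error if `TRUE` (default), fail with an informative error when
#'   any check is violated; otherwise return the report with `ok = FALSE`.
#' @return invisibly, a list with `ok`, a data.frame `checks` (one row per
#'   audited quantity: value, bound, slack, ok), and the recomputed
#'   `decomposition`.
#' @export
audit_solution <- function(solution, farm, spec, tol = 1e-6, error = TRUE) {
  stopifnot(inherits(solution, "farm_solution"))
  if (solution$status != "optimal") stop("can only audit an optimal solution", call. = FALSE)
  r_unit <- as.integer(t(solution$frequency))
  s_unit <- as.integer(t(solution$seed))
  dec <- compute_decomposition(farm, r_unit, s_unit)
  prob <- build_problem(farm, spec)

  checks <- data.frame(
    check = "objective_consistency",
    value = dec$objective,
    bound = solution$objective,
    slack = abs(dec$objective - solution$objective),
    ok = abs(dec$objective - solution$objective) <=
      tol * max(1, abs(solution$objective)),
    stringsAsFactors = FALSE
  )

  opt_cell_idx <- cbind(
    option_index(r_unit, s_unit, prob$R, prob$S),
    unit_soil(farm$grid)
  )
  lhs_tables <- list(
    irrigation_budget = farm$catalog$C_f * farm$grid$unit_area +
      farm$catalog$W * farm$econ$water_price / farm$econ$gamma,
    operating_budget = farm$catalog$C_m * farm$grid$unit_area,
    min_yield = farm$catalog$Y * farm$grid$unit_area,
    water_limit = farm$catalog$W / farm$econ$gamma
  )
  bounds <- prob$bounds
  rhs <- c(
    irrigation_budget = bounds$irrigation_budget,
    operating_budget = bounds$operating_budget,
    min_yield = bounds$min_yield,
    water_limit = bounds$water_limit * farm$econ$area -
      farm$econ$pre_irrigation * farm$econ$area
  )
  for (nm in names(lhs_tables)) {
    lhs <- sum(lhs_tables[[nm]][opt_cell_idx])
    lim <- rhs[[nm]]
    if (nm == "min_yield") {
      slack <- lhs - lim
    } else {
      slack <- lim - lhs
    }
    checks <- rbind(checks, data.frame(
      check = nm, value = lhs, bound = lim, slack = slack,
      ok = !is.finite(lim) || slack >= -tol * max(1, abs(lim)),
      stringsAsFactors = FALSE
    ))
  }

  parts <- resolve_partitions(farm, spec)
  uniform_in <- function(mem, v) all(tapply(v, mem, function(x) length(unique(x)) == 1L))
  checks <- rbind(checks, data.frame(
    check = c("seed_uniform_in_decision_units", "irrigation_uniform_in_decision_units",
      "one_decision_per_unit"),
    value = NA_real_, bound = NA_real_, slack = NA_real_,
    ok = c(
      uniform_in(partition_membership(parts$seed), s_unit),
      uniform_in(partition_membership(parts$irrigation), r_unit),
      !anyNA(r_unit) && !anyNA(s_unit)
    ),
    stringsAsFactors = FALSE
  ))

  out <- list(ok = all(checks$ok), checks = checks, decomposition = dec)
  if (!out$ok && error) {
    stop("solution audit failed: ",
      paste(checks$check[!checks$ok], collapse = ", "), call. = FALSE)
  }
  invisible(out)
}
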