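#' Farm-level economic parameters
#'
#' Bundles every scalar that prices the management plan: crop and residue
#' prices, water price, overhead, the residue/sustainability/efficiency
#' coefficients, and the optional budget, yield, and water bounds used by
#' the planning model's side constraints.
#'
#' @param area total farm area (ha). Validated against `n_units * unit_area`
#'   of the soil grid (2\% tolerance, warning only) when a model is built.
#' @param corn_price grain price P ($/t).
#' @param residue_price price for unharvested residue ($/t).
#' @param water_price irrigation water price ($/m3 purchased).
#' @param overhead_cost farm overhead, cash plus non-cash ($/ha); applied to
#'   the whole farm independent of management decisions.
#' @param alpha residues index: mass ratio of grain to total above-ground
#'   biomass, in (0, 1). `alpha = 0.5` means stover mass equals grain mass.
#' @param beta sustainability factor: fraction of residue that must stay on
#'   the field, in \[0, 1\].
#' @param gamma water-use efficiency: ratio of water reaching the crop to
#'   water purchased, in (0, 1\]. Purchases scale as applied water / gamma.
#' @param irrigation_budget budget for irrigation (fixed cost + water) ($);
#'   `Inf` disables the constraint.
#' @param operating_budget budget for other farm operating cost ($); `Inf`
#'   disables the constraint.
#' @param min_yield minimum total farm yield (t); `0` disables.
#' @param water_limit seasonal limit on purchased water, per unit area
#'   (m3/ha); multiplied by `area` to give the farm-level bound. `Inf`
#'   disables.
#' @param pre_irrigation pre-season irrigation, per unit area (m3/ha);
#'   counts against the seasonal water limit but not the objective.
#' @return an object of class `economic_params`.
#' @seealso [default_economics()] for the calibrated case-study values.
#' @export
economic_params <- function(area,
                            corn_price,
                            residue_price,
                            water_price,
                            overhead_cost,
                            alpha = 0.5,
                            beta = 0.3,
                            gamma = 0.6,
                            irrigation_budget = Inf,
                            operating_budget = Inf,
                            min_yield = 0,
                            water_limit = Inf,
                            pre_irrigation = 0) {
  econ <- list(
    area = area, corn_price = corn_price, residue_price = residue_price,
    water_price = water_price, overhead_cost = overhead_cost,
    alpha = alpha, beta = beta, gamma = gamma,
    irrigation_budget = irrigation_budget,
    operating_budget = operating_budget,
    min_yield = min_yield, water_limit = water_limit,
    pre_irrigation = pre_irrigation
  )
  validate_economic_params(econ)
  structure(econ, class = "economic_params")
}

validate_economic_params <- function(econ) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  for (f in names(econ)) {
    if (!num1(econ[[f]])) stop("economic parameter `", f, "` must be a single number", call. = FALSE)
  }
  if (!(econ$gamma > 0 && econ$gamma <= 1)) stop("gamma must lie in (0, 1]", call. = FALSE)
  if (!(econ$beta >= 0 && econ$beta <= 1)) stop("beta must lie in [0, 1]", call. = FALSE)
  if (!(econ$alpha > 0 && econ$alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  nonneg <- c(
    "area", "corn_price", "residue_price", "water_price", "overhead_cost",
    "irrigation_budget", "operating_budget", "min_yield", "water_limit",
    "pre_irrigation"
  )
  for (f in nonneg) {
    if (econ[[f]] < 0) stop("economic parameter `", f, "` must be non-negative", call. = FALSE)
  }
  invisible(econ)
}

#' Case-study economics for an irrigated California corn farm
#'
#' Returns the baseline parameterization used throughout the examples and
#' tests: a 65.56 ha farm, corn at $141/t, residue at $35/t, water at
#' $0.073/m3 ($90/acre-foot), water-use efficiency 0.6, residues index 0.5,
#' sustainability factor 0.3, a pre-irrigation of 8 acre-inches, and a
#' seasonal purchased-water allotment of 2.5 acre-feet per acre. Overhead
#' (cash plus non-cash) defaults to $180/ha; it is a synthetic calibration
#' value, chosen so a uniformly managed baseline remains modestly
#' profitable at the baseline corn price.
#'
#' @param ... named overrides for any [economic_params()] argument.
#' @return an `economic_params` object.
#' @export
default_economics <- function(...) {
  base <- list(
    area = 65.56,
    corn_price = 141,
    residue_price = 35,
    water_price = 0.073,
    overhead_cost = 180,
    alpha = 0.5,
    beta = 0.3,
    gamma = 0.6,
    irrigation_budget = Inf,
    operating_budget = Inf,
    min_yield = 0,
    water_limit = per_acre_to_per_ha(acre_feet_to_m3(2.5)),
    pre_irrigation = per_acre_to_per_ha(ACRE_INCH_TO_M3 * 8)
  )
  do.call(economic_params, modifyList(base, list(...)))
}

#' @export
print.economic_params <- function(x, ...) {
  cat("Farm economics\n")
  cat(sprintf("  area            A    %10.2f ha\n", x$area))
  cat(sprintf("  corn price      P    %10.2f $/t\n", x$corn_price))
  cat(sprintf("  residue price   Rb   %10.2f $/t\n", x$residue_price))
  cat(sprintf("  water price     Cw   %10.4f $/m3\n", x$water_price))
  cat(sprintf("  overhead        Co   %10.2f $/ha\n", x$overhead_cost))
  cat(sprintf("  alpha / beta / gamma %.2f / %.2f / %.2f\n", x$alpha, x$beta, x$gamma))
  cat(sprintf("  water limit     Wl   %10.2f m3/ha\n", x$water_limit))
  cat(sprintf("  pre-irrigation  Wp   %10.2f m3/ha\n", x$pre_irrigation))
  if (is.finite(x$irrigation_budget)) cat(sprintf("  irrigation budget    %10.2f $\n", x$irrigation_budget))
  if (is.finite(x$operating_budget)) cat(sprintf("  operating budget     %10.2f $\n", x$operating_budget))
  if (x$min_yield > 0) cat(sprintf("  minimum yield        %10.2f t\n", x$min_yield))
  invisible(x)
}
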