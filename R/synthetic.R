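# Seeded synthetic-farm generator -------------------------------------------
#
# Emulates the case-study farm: an 18 x 18 grid of half-acre land units
# carrying five soil classes in contiguous patches, six irrigation
# frequencies, and twelve corn hybrids in four drought-resistance classes.
# The published study never prints its yield/water tables, so this module
# derives them from a small water-balance model with documented, synthetic
# defaults; every quantity is a pure function of the recipe.

#' Recipe for a synthetic farm
#'
#' Collects every knob of the generator. Equal recipes always generate
#' byte-identical farms; the RNG seed is explicit and global RNG state is
#' never touched.
#'
#' @param seed integer RNG seed.
#' @param n_rows,n_cols land-unit grid dimensions.
#' @param n_classes number of soil classes (1-6).
#' @param blob_count number of contiguous soil patches grown on the fine
#'   raster; must not exceed the number of fine cells.
#' @param fine_factor fine raster resolution: each land unit covers
#'   `fine_factor^2` survey cells, integrated by majority vote.
#' @param class_weights sampling weights of soil classes over patches
#'   (recycled/normalized); the default skews sandy, as on the case farm.
#' @param unit_area land-unit area (ha).
#' @param season_days irrigated-season length (days).
#' @param water_need seasonal applied-water requirement for a fully watered
#'   crop (m3/ha); the default corresponds to the crop's seasonal
#'   evapotranspiration net of pre-season soil moisture.
#' @param survival_water minimum seasonal applied water for crop survival.
#' @param survival_basis `"per_hectare"` (default) or `"per_acre"`: the
#'   area basis on which `survival_water` is quoted.
#' @param cost_per_event fixed irrigation labor/equipment cost per event
#'   ($/ha); surge sets must be walked and switched at every irrigation.
#' @param operating_cost other farm operating cost for planted options
#'   ($/ha); machinery, labor, seed and chemicals, uniformly applied.
#' @param yield_range admissible envelope (t/ha) for hybrid peak yields.
#' @param economics an [economic_params()] object.
#' @return an object of class `farm_recipe`.
#' @export
farm_recipe <- function(seed = 1L,
                        n_rows = 18L, n_cols = 18L,
                        n_classes = 5L, blob_count = 12L,
                        fine_factor = 3L,
                        class_weights = c(0.30, 0.20, 0.20, 0.15, 0.15),
                        unit_area = acres_to_ha(0.5),
                        season_days = 105L,
                        water_need = 3600,
                        survival_water = 1131,
                        survival_basis = c("per_hectare", "per_acre"),
                        cost_per_event = 35,
                        operating_cost = 1333,
                        yield_range = c(13.17, 18.81),
                        economics = default_economics()) {
  survival_basis <- match.arg(survival_basis)
  stopifnot(
    n_classes >= 1, n_classes <= 6,
    blob_count >= n_classes,
    blob_count <= n_rows * n_cols * fine_factor^2,
    fine_factor >= 1,
    water_need > 0, season_days > 0,
    length(yield_range) == 2L, yield_range[1] <= yield_range[2]
  )
  class_weights <- rep_len(class_weights, n_classes)
  class_weights <- class_weights / sum(class_weights)
  structure(
    list(
      seed = as.integer(seed), n_rows = as.integer(n_rows),
      n_cols = as.integer(n_cols), n_classes = as.integer(n_classes),
      blob_count = as.integer(blob_count), fine_factor = as.integer(fine_factor),
      class_weights = class_weights, unit_area = unit_area,
      season_days = as.integer(season_days), water_need = water_need,
      survival_water = survival_water, survival_basis = survival_basis,
      cost_per_event = cost_per_event, operating_cost = operating_cost,
      yield_range = yield_range, economics = economics
    ),
    class = "farm_recipe"
  )
}

#' Generate a fine soil raster and its integrated land-unit grid
#'
#' Grows `blob_count` contiguous soil patches by seeded random region
#' growing on the fine raster, then integrates to the land-unit grid by
#' majority vote. The first `n_classes` patches receive each soil class
#' once (so every class occurs); remaining patches draw classes with
#' `class_weights`.
#'
#' @param recipe a [farm_recipe()].
#' @return list with `raster` (fine integer matrix) and `grid` (a
#'   [soil_grid()]).
#' @export
generate_soil_raster <- function(recipe) {
  Mf <- recipe$n_rows * recipe$fine_factor
  Nf <- recipe$n_cols * recipe$fine_factor
  J <- recipe$n_classes
  nb <- recipe$blob_count
  raster <- with_local_seed(recipe$seed, {
    cells <- rep(NA_integer_, Mf * Nf)
    starts <- sample.int(Mf * Nf, nb)
    blob_class <- c(
      sample.int(J),
      if (nb > J) sample.int(J, nb - J, replace = TRUE, prob = recipe$class_weights)
    )
    cells[starts] <- blob_class
    # randomized multi-source growth: repeatedly extend the assigned region
    # by one unassigned 4-neighbour, chosen uniformly over the frontier
    frontier <- starts
    n_front <- nb
    nbr <- function(idx) {
      r <- (idx - 1L) %% Mf + 1L
      k <- (idx - 1L) %/% Mf + 1L
      out <- c(
        if (r > 1L) idx - 1L, if (r < Mf) idx + 1L,
        if (k > 1L) idx - Mf, if (k < Nf) idx + Mf
      )
      out
    }
    while (n_front > 0L) {
      pick <- sample.int(n_front, 1L)
      f <- frontier[pick]
      free <- nbr(f)
      free <- free[is.na(cells[free])]
      if (length(free) == 0L) {
        frontier[pick] <- frontier[n_front]
        n_front <- n_front - 1L
      } else {
        g <- if (length(free) == 1L) free else free[sample.int(length(free), 1L)]
        cells[g] <- cells[f]
        n_front <- n_front + 1L
        frontier[n_front] <- g
      }
    }
    matrix(cells, Mf, Nf)
  })
  classes <- soil_classes(J)
  integrated <- majority_vote_downsample(raster, recipe$fine_factor)
  list(
    raster = raster,
    grid = soil_grid(integrated, unit_area = recipe$unit_area, classes = classes)
  )
}

# Adequacy of frequency r on soil j: the fraction of crop water demand the
# soil can buffer between events. demand_rate = water_need / season_days;
# an event refills at most refill_depth(j), and never more than what the
# crop drew since the last event.
adequacy_fraction <- function(refill_depth, interval_days, demand_rate) {
  pmin(1, refill_depth / (demand_rate * interval_days))
}

#' Derive the agronomic and cost tables of a synthetic farm
#'
#' Builds the `Y`, `W`, `C_f`, `C_m` tables of the management catalogue
#' from a simple per-soil water balance. Writing `d` for the daily crop
#' water demand (`water_need / season_days`) and `q_j` for the per-event
#' refill of soil `j`:
#' * applied water per event is `min(q_j, d * interval_r)` (soils refill to
#'   saturation, but never beyond what was depleted);
#' * seasonal applied water `W` is events x per-event volume, scaled to one
#'   land unit;
#' * irrigation adequacy is `min(1, q_j / (d * interval_r))`, a
#'   nonincreasing function of the interval, reaching 1 sooner on heavier
#'   soils (sandier soils need more frequent irrigation);
#' * yield is `max_yield * adequacy^sensitivity`, and zero whenever the
#'   seasonal applied water falls below the hybrid's survival requirement
#'   or the option is fallow (irrigation stops when the crop is dead).
#'
#' @param recipe a [farm_recipe()].
#' @param soils,seeds,frequencies optional component tables; defaults are
#'   [soil_classes()], [seed_hybrids()], [irrigation_frequencies()]
#'   parameterized from the recipe.
#' @return a [management_catalog()].
#' @export
derive_agronomic_table <- function(recipe,
                                   soils = soil_classes(recipe$n_classes),
                                   seeds = NULL,
                                   frequencies = irrigation_frequencies(recipe$season_days)) {
  survival <- recipe$survival_water
  if (recipe$survival_basis == "per_acre") survival <- per_acre_to_per_ha(survival)
  if (is.null(seeds)) seeds <- seed_hybrids(survival_water = survival)
  if (any(seeds$max_yield < recipe$yield_range[1] - 1e-9) ||
      any(seeds$max_yield > recipe$yield_range[2] + 1e-9)) {
    stop("seed peak yields fall outside the recipe's yield envelope", call. = FALSE)
  }
  R <- nrow(frequencies); S <- nrow(seeds); J <- nrow(soils)
  demand_rate <- recipe$water_need / recipe$season_days

  # per-frequency x soil: seasonal applied water (m3/ha) and adequacy
  W_ha <- matrix(0, R, J)
  adq <- matrix(0, R, J)
  for (r in seq_len(R)) {
    if (frequencies$events[r] == 0L) next
    iv <- frequencies$interval_days[r]
    per_event <- pmin(soils$refill_depth, demand_rate * iv)
    W_ha[r, ] <- frequencies$events[r] * per_event
    adq[r, ] <- adequacy_fraction(soils$refill_depth, iv, demand_rate)
  }

  I <- R * S
  Y <- matrix(0, I, J)
  W <- matrix(0, I, J)
  C_f <- matrix(0, I, J)
  C_m <- matrix(0, I, J)
  for (r in seq_len(R)) {
    for (s in seq_len(S)) {
      i <- option_index(r, s, R, S)
      if (frequencies$events[r] == 0L) next # fallow: all zeros
      y <- seeds$max_yield[s] * adq[r, ]^seeds$sensitivity[s]
      y[W_ha[r, ] < seeds$survival_water[s]] <- 0
      Y[i, ] <- y
      W[i, ] <- W_ha[r, ] * recipe$unit_area # volume per land unit
      C_f[i, ] <- frequencies$events[r] * recipe$cost_per_event
      C_m[i, ] <- recipe$operating_cost
    }
  }
  management_catalog(frequencies, seeds, soils, Y, W, C_f, C_m)
}

#' Generate a complete synthetic farm
#'
#' One-stop constructor: soil raster and grid, management catalogue, and
#' economics, all determined by the recipe.
#'
#' @param recipe a [farm_recipe()].
#' @return an object of class `farm`: list with `recipe`, `raster`, `grid`,
#'   `catalog`, `econ`.
#' @examples
#' farm <- synthetic_farm(farm_recipe(seed = 7))
#' farm
#' @export
synthetic_farm <- function(recipe = farm_recipe()) {
  gen <- generate_soil_raster(recipe)
  catalog <- derive_agronomic_table(recipe, soils = gen$grid$classes)
  structure(
    list(
      recipe = recipe, raster = gen$raster, grid = gen$grid,
      catalog = catalog, econ = recipe$economics
    ),
    class = "farm"
  )
}

#' Assemble a farm from existing components
#'
#' For farms read from files rather than generated: combines a soil grid,
#' a management catalogue, and economics into the `farm` container used by
#' the solver and analyses.
#'
#' @param grid a [soil_grid()].
#' @param catalog a [management_catalog()].
#' @param econ an [economic_params()].
#' @return a `farm` object.
#' @export
farm_from_parts <- function(grid, catalog, econ) {
  if (nrow(catalog$soils) < nrow(grid$classes)) {
    stop("catalogue covers fewer soil classes than the grid", call. = FALSE)
  }
  structure(
    list(recipe = NULL, raster = NULL, grid = grid, catalog = catalog, econ = econ),
    class = "farm"
  )
}

#' @export
print.farm <- function(x, ...) {
  cat("Synthetic farm\n")
  print(x$grid)
  print(x$catalog)
  invisible(x)
}
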