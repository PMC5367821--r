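# Configuration and file I/O -------------------------------------------------

# Allowed units per economics key, with factors converting to the internal
# SI frame (ha, m3, t, USD). The first unit listed is the canonical one
# used when saving.
econ_units <- function() {
  list(
    area = c("ha" = 1, "acre" = ACRE_TO_HA),
    corn_price = c("USD/t" = 1),
    residue_price = c("USD/t" = 1),
    water_price = c("USD/m3" = 1, "USD/acre_ft" = 1 / ACRE_FOOT_TO_M3),
    overhead_cost = c("USD/ha" = 1, "USD/acre" = 1 / ACRE_TO_HA),
    alpha = c("1" = 1),
    beta = c("1" = 1),
    gamma = c("1" = 1),
    irrigation_budget = c("USD" = 1),
    operating_budget = c("USD" = 1),
    min_yield = c("t" = 1),
    water_limit = c(
      "m3/ha" = 1, "m3/acre" = 1 / ACRE_TO_HA,
      "acre_ft/acre" = ACRE_FOOT_TO_M3 / ACRE_TO_HA
    ),
    pre_irrigation = c(
      "m3/ha" = 1, "m3/acre" = 1 / ACRE_TO_HA,
      "acre_in/acre" = ACRE_INCH_TO_M3 / ACRE_TO_HA
    )
  )
}

# Parse "141", 141, or "141 USD/t" into an SI number for `key`.
parse_quantity <- function(x, key) {
  units <- econ_units()[[key]]
  if (is.numeric(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (x %in% c("Inf", ".inf")) return(Inf)
    parts <- strsplit(trimws(x), "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(val)) {
      stop("economics key `", key, "` has non-numeric value \"", x, "\"", call. = FALSE)
    }
    if (length(parts) == 1L) return(val)
    unit <- paste(parts[-1], collapse = " ")
    if (!unit %in% names(units)) {
      stop("economics key `", key, "` has unknown unit \"", unit,
        "\" (expected one of: ", paste(names(units), collapse = ", "), ")",
        call. = FALSE)
    }
    return(val * units[[unit]])
  }
  stop("economics key `", key, "` must be a number or \"value unit\" string", call. = FALSE)
}

RECIPE_KEYS <- c(
  "seed", "n_rows", "n_cols", "n_classes", "blob_count", "fine_factor",
  "class_weights", "unit_area", "season_days", "water_need",
  "survival_water", "survival_basis", "cost_per_event", "operating_cost",
  "yield_range"
)
MODEL_KEYS <- c(
  "variant", "n_units", "shape", "seed_n_units", "seed_shape",
  "irrigation_n_units", "irrigation_shape"
)
SOLVER_KEYS <- c("node_cap", "tol", "seed")

check_keys <- function(x, allowed, section) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown ", section, " key(s): ", paste(bad, collapse = ", "),
      " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
}

#' Load a run configuration
#'
#' Reads a YAML configuration describing the farm (a soil-grid file and/or
#' a synthetic-farm recipe), the economics, the model variant and
#' partitions, and solver settings. Economics values may carry unit
#' suffixes (`"141 USD/t"`, `"2.5 acre_ft/acre"`); every value is
#' converted to the internal SI frame exactly once, at load. Unknown keys
#' are rejected with the list of allowed keys.
#'
#' @param path path to a YAML file.
#' @return an object of class `run_config`: list with elements `farm`
#'   (`soil_grid` path and/or `recipe` list), `economics` (an
#'   [economic_params()]), `model`, `solver`, `output`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  check_keys(raw, c("farm", "economics", "model", "solver", "output"), "top-level")

  farm <- raw$farm %||% list()
  check_keys(farm, c("soil_grid", "recipe"), "farm")
  if (!is.null(farm$recipe)) check_keys(farm$recipe, RECIPE_KEYS, "farm recipe")

  econ_raw <- raw$economics %||% list()
  check_keys(econ_raw, names(econ_units()), "economics")
  econ_args <- lapply(
    setNames(names(econ_raw), names(econ_raw)),
    function(k) parse_quantity(econ_raw[[k]], k)
  )
  econ <- do.call(default_economics, econ_args)
  attr(econ, "area_explicit") <- "area" %in% names(econ_raw)

  model <- raw$model %||% list()
  check_keys(model, MODEL_KEYS, "model")
  solver <- raw$solver %||% list()
  check_keys(solver, SOLVER_KEYS, "solver")

  structure(
    list(
      farm = farm, economics = econ, model = model, solver = solver,
      output = raw$output
    ),
    class = "run_config"
  )
}

#' Save a run configuration
#'
#' Writes the canonical SI form of a configuration; loading the result
#' reproduces the configuration exactly (load -> save -> load is the
#' identity).
#'
#' @param config a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  econ <- unclass(config$economics)
  econ <- lapply(econ, function(v) if (is.infinite(v)) "Inf" else v)
  out <- list(
    farm = config$farm,
    economics = econ,
    model = config$model,
    solver = config$solver,
    output = config$output
  )
  out <- Filter(function(x) !is.null(x) && (length(x) > 0L), out)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Build a farm from a configuration
#'
#' If the configuration carries a recipe, the synthetic generator is used
#' (reading the soil grid from file instead, when one is given, so a
#' generated farm round-trips through disk). The agronomic tables are
#' always derived from the recipe, since soil-grid files carry no yield
#' information.
#'
#' @param config a `run_config`.
#' @param base_dir directory against which relative paths are resolved.
#' @return a `farm` object.
#' @export
config_farm <- function(config, base_dir = ".") {
  recipe_args <- config$farm$recipe %||% list()
  if (!is.null(recipe_args$yield_range)) {
    recipe_args$yield_range <- as.numeric(recipe_args$yield_range)
  }
  if (!is.null(recipe_args$class_weights)) {
    recipe_args$class_weights <- as.numeric(recipe_args$class_weights)
  }
  recipe <- do.call(farm_recipe, c(recipe_args, list(economics = config$economics)))
  if (!is.null(config$farm$soil_grid)) {
    p <- config$farm$soil_grid
    if (!file.exists(p)) p <- file.path(base_dir, config$farm$soil_grid)
    grid <- read_soil_grid(p,
      unit_area = recipe$unit_area,
      classes = soil_classes(recipe$n_classes)
    )
    catalog <- derive_agronomic_table(recipe, soils = grid$classes)
    farm <- farm_from_parts(grid, catalog, config$economics)
  } else {
    farm <- synthetic_farm(recipe)
  }
  # unless the configuration pins the farm area, take it from the grid
  if (!isTRUE(attr(config$economics, "area_explicit"))) {
    farm$econ$area <- n_units(farm$grid) * farm$grid$unit_area
  }
  farm
}

#' Resolve the model specification of a configuration
#'
#' @param config a `run_config`.
#' @param n_rows,n_cols grid dimensions the partitions must tile.
#' @return a [model_spec()].
#' @export
config_model_spec <- function(config, n_rows, n_cols) {
  m <- config$model
  variant <- m$variant %||% "I"
  if (variant == "I") return(model_spec("I"))
  if (variant == "II") {
    part <- make_partition(n_rows, n_cols, m$n_units %||% 1, m$shape %||% "square")
    return(model_spec("II", partition = part))
  }
  model_spec("III",
    seed_partition = make_partition(n_rows, n_cols,
      m$seed_n_units %||% 1, m$seed_shape %||% "square"),
    irrigation_partition = make_partition(n_rows, n_cols,
      m$irrigation_n_units %||% 1, m$irrigation_shape %||% "square")
  )
}

#' Read / write a soil-grid file
#'
#' Plain-text format: one line per grid row (row 1 = north edge),
#' whitespace- or comma-separated integer soil-class ids, 1-based.
#' Write-then-read is the identity.
#'
#' @param path file path.
#' @param unit_area,classes metadata attached to the grid on read (the
#'   file itself carries only class ids).
#' @return `read_soil_grid()`: a [soil_grid()]; `write_soil_grid()`:
#'   `path`, invisibly.
#' @export
read_soil_grid <- function(path, unit_area = acres_to_ha(0.5), classes = NULL) {
  if (!file.exists(path)) stop("soil grid file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("soil grid file is empty: ", path, call. = FALSE)
  rows <- lapply(seq_along(lines), function(ln) {
    toks <- strsplit(trimws(lines[ln]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.integer(toks))
    if (anyNA(vals)) {
      stop("non-integer soil id on line ", ln, " of ", path, call. = FALSE)
    }
    vals
  })
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop("ragged soil grid: line ", bad, " has ", widths[bad],
      " cells, expected ", widths[1], call. = FALSE)
  }
  cells <- do.call(rbind, rows)
  if (any(cells < 1L)) {
    stop("soil-class ids are 1-based; found id ", min(cells), call. = FALSE)
  }
  soil_grid(cells, unit_area = unit_area, classes = classes)
}

#' @rdname read_soil_grid
#' @param grid a [soil_grid()] to write.
#' @export
write_soil_grid <- function(grid, path) {
  writeLines(apply(grid$cells, 1, paste, collapse = " "), path)
  invisible(path)
}

#' Write an analysis table as deterministic CSV
#'
#' Column order is preserved, doubles are printed with six fixed decimals,
#' and no row names are emitted, so identical inputs give byte-identical
#' files. An empty table yields a header-only file.
#'
#' @param results a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- as.data.frame(results)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.6f", out[[nm]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
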