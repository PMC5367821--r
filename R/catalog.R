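# Irrigation frequencies, seed hybrids, and the management-option catalog ---

#' The irrigation frequency ladder
#'
#' Six frequencies span the practical range for surge irrigation over a
#' 15-week irrigated season: daily, weekly, every two / three / four weeks,
#' and never (the fallow choice). Exactly one frequency has zero events.
#'
#' @param season_days length of the irrigated season in days.
#' @return data.frame with columns `id`, `label`, `interval_days` (`NA` for
#'   never), and `events` (irrigation events per season).
#' @export
irrigation_frequencies <- function(season_days = 105) {
  intervals <- c(1, 7, 14, 21, 28)
  out <- data.frame(
    id = 1:6,
    label = c("daily", "weekly", "two_weekly", "three_weekly", "four_weekly", "never"),
    interval_days = c(intervals, NA),
    events = c(as.integer(ceiling(season_days / intervals)), 0L),
    stringsAsFactors = FALSE
  )
  stopifnot(sum(out$events == 0L) == 1L, !is.unsorted(rev(out$events), strictly = TRUE))
  out
}

#' The candidate seed hybrids
#'
#' Twelve grain-corn hybrids, three in each of four drought-resistance
#' classes. `max_yield` is the yield under fully adequate irrigation;
#' `sensitivity` is the exponent of the yield response to the irrigation
#' adequacy fraction (higher = yield collapses faster under deficit);
#' `survival_water` is the minimum seasonal applied water per unit area
#' below which the crop dies.
#'
#' The classes trade peak yield against drought tolerance: `stringy`
#' hybrids are cheap low-enders, `drought` hybrids tolerate long intervals,
#' `smart` hybrids balance both, and `extravagant` hybrids yield most but
#' demand fully adequate water. Peak yields span 13.17 to 18.81 t/ha.
#'
#' @param survival_water minimum seasonal applied water (m3/ha) for the
#'   crop to survive; applied to all hybrids.
#' @return data.frame with columns `id`, `name`, `class`, `max_yield`,
#'   `sensitivity`, `survival_water`.
#' @export
seed_hybrids <- function(survival_water = 1131) {
  classes <- c("stringy", "drought", "smart", "extravagant")
  out <- data.frame(
    id = 1:12,
    name = paste0(rep(classes, each = 3), "_", rep(1:3, times = 4)),
    class = rep(classes, each = 3),
    max_yield = c(
      13.17, 13.62, 14.05,  # stringy
      14.20, 14.70, 15.20,  # drought
      15.80, 16.40, 17.00,  # smart
      17.80, 18.30, 18.81   # extravagant
    ),
    sensitivity = rep(c(1.2, 0.45, 0.75, 1.7), each = 3),
    survival_water = survival_water,
    stringsAsFactors = FALSE
  )
  out
}

#' Map a (frequency, seed) pair to its management-option id and back
#'
#' Management options enumerate the Cartesian product of `R` irrigation
#' frequencies and `S` seed types in row-major order:
#' `i = (r - 1) * S + s`. The map is a bijection onto `1..R*S`.
#'
#' @param r irrigation frequency id in `1..n_frequencies`.
#' @param s seed id in `1..n_seeds`.
#' @param n_frequencies,n_seeds catalogue dimensions.
#' @return `option_index()`: the option id `i`; `option_rs()`: a list with
#'   elements `r` and `s`.
#' @export
option_index <- function(r, s, n_frequencies = 6, n_seeds = 12) {
  if (any(r < 1 | r > n_frequencies)) stop("frequency id out of range 1..", n_frequencies, call. = FALSE)
  if (any(s < 1 | s > n_seeds)) stop("seed id out of range 1..", n_seeds, call. = FALSE)
  (as.integer(r) - 1L) * as.integer(n_seeds) + as.integer(s)
}

#' @rdname option_index
#' @param i management-option id in `1..n_frequencies * n_seeds`.
#' @export
option_rs <- function(i, n_frequencies = 6, n_seeds = 12) {
  if (any(i < 1 | i > n_frequencies * n_seeds)) {
    stop("option id out of range 1..", n_frequencies * n_seeds, call. = FALSE)
  }
  i <- as.integer(i)
  list(r = (i - 1L) %/% as.integer(n_seeds) + 1L, s = (i - 1L) %% as.integer(n_seeds) + 1L)
}

#' Assemble the management-option catalogue
#'
#' The catalogue holds the agronomic and cost tables indexed by management
#' option `i` (rows, one per frequency x seed pair) and soil class `j`
#' (columns): yield `Y` (t/ha), seasonal applied irrigation water `W`
#' (m3 per land unit), fixed irrigation labor/equipment cost `C_f` ($/ha),
#' and other operating cost `C_m` ($/ha).
#'
#' Options whose frequency is "never" are fallow: zero water, zero yield,
#' and (by convention) zero operating and irrigation cost, so leaving a
#' unit idle is representable while still assigning exactly one option.
#'
#' @param frequencies data.frame from [irrigation_frequencies()].
#' @param seeds data.frame from [seed_hybrids()].
#' @param soils data.frame from [soil_classes()].
#' @param Y,W,C_f,C_m numeric `I x J` tables as described above.
#' @return an object of class `management_catalog`.
#' @export
management_catalog <- function(frequencies, seeds, soils, Y, W, C_f, C_m) {
  R <- nrow(frequencies); S <- nrow(seeds); J <- nrow(soils)
  I <- R * S
  options <- data.frame(
    i = seq_len(I),
    r = rep(seq_len(R), each = S),
    s = rep(seq_len(S), times = R)
  )
  for (nm in c("Y", "W", "C_f", "C_m")) {
    tab <- get(nm)
    if (!is.matrix(tab) || nrow(tab) != I || ncol(tab) != J) {
      stop("table `", nm, "` must be a ", I, " x ", J, " matrix", call. = FALSE)
    }
    if (any(tab < 0)) stop("table `", nm, "` has negative entries", call. = FALSE)
  }
  fallow <- options$i[frequencies$events[options$r] == 0L]
  if (any(W[fallow, ] != 0) || any(Y[fallow, ] != 0)) {
    stop("options with the 'never' frequency must have zero water and yield", call. = FALSE)
  }
  structure(
    list(
      frequencies = frequencies, seeds = seeds, soils = soils,
      options = options, Y = Y, W = W, C_f = C_f, C_m = C_m
    ),
    class = "management_catalog"
  )
}

#' @export
print.management_catalog <- function(x, ...) {
  cat(sprintf(
    "Management catalogue: %d options (%d frequencies x %d seeds) on %d soil classes\n",
    nrow(x$options), nrow(x$frequencies), nrow(x$seeds), nrow(x$soils)
  ))
  cat(sprintf("  yield range %.2f-%.2f t/ha, applied water up to %.0f m3/unit\n",
    min(x$Y[x$Y > 0]), max(x$Y), max(x$W)))
  invisible(x)
}

#' Per-unit profit of one management option on one soil class
#'
#' Decomposes the annual net contribution of a single land unit managed
#' with option `i` on soil `j` into grain revenue, residue revenue,
#' operating cost, water purchase cost, and fixed irrigation cost:
#' \deqn{net = Y_{ij} E P + Y_{ij} E \alpha (1-\beta) R_b / (1-\alpha)
#'   - C^m_{ij} E - C^f_{ij} E - W_{ij} C^w / \gamma.}
#' Farm overhead is a whole-farm constant and deliberately excluded here.
#'
#' @param catalog a [management_catalog()].
#' @param econ an [economic_params()].
#' @param i management-option id.
#' @param j soil-class id.
#' @param unit_area land-unit area E (ha).
#' @return an object of class `unit_economics`: list with the five
#'   components and their `net`.
#' @export
unit_profit <- function(catalog, econ, i, j, unit_area) {
  I <- nrow(catalog$options); J <- nrow(catalog$soils)
  if (i < 1 || i > I) stop("option id out of range 1..", I, call. = FALSE)
  if (j < 1 || j > J) stop("soil id out of range 1..", J, call. = FALSE)
  E <- unit_area
  Y <- catalog$Y[i, j]; W <- catalog$W[i, j]
  comp <- list(
    revenue_grain = Y * E * econ$corn_price,
    revenue_residue = Y * E * econ$alpha * (1 - econ$beta) * econ$residue_price / (1 - econ$alpha),
    cost_operating = catalog$C_m[i, j] * E,
    cost_water = W * econ$water_price / econ$gamma,
    cost_irrigation_fixed = catalog$C_f[i, j] * E
  )
  comp$net <- comp$revenue_grain + comp$revenue_residue -
    comp$cost_operating - comp$cost_water - comp$cost_irrigation_fixed
  structure(comp, class = "unit_economics")
}

#' @export
print.unit_economics <- function(x, ...) {
  cat("Per-unit economics ($):\n")
  cat(sprintf("  grain revenue      %10.2f\n", x$revenue_grain))
  cat(sprintf("  residue revenue    %10.2f\n", x$revenue_residue))
  cat(sprintf("  operating cost     %10.2f\n", x$cost_operating))
  cat(sprintf("  water cost         %10.2f\n", x$cost_water))
  cat(sprintf("  irrigation fixed   %10.2f\n", x$cost_irrigation_fixed))
  cat(sprintf("  net                %10.2f\n", x$net))
  invisible(x)
}

# I x J matrices of the five objective components plus net profit, one
# entry per (option, soil) pair. Used to assemble objectives in bulk.
profit_tables <- function(catalog, econ, unit_area) {
  E <- unit_area
  list(
    revenue_grain = catalog$Y * E * econ$corn_price,
    revenue_residue = catalog$Y * E * econ$alpha * (1 - econ$beta) *
      econ$residue_price / (1 - econ$alpha),
    cost_operating = catalog$C_m * E,
    cost_water = catalog$W * econ$water_price / econ$gamma,
    cost_irrigation_fixed = catalog$C_f * E
  )
}

profit_matrix <- function(catalog, econ, unit_area) {
  tabs <- profit_tables(catalog, econ, unit_area)
  tabs$revenue_grain + tabs$revenue_residue - tabs$cost_operating -
    tabs$cost_water - tabs$cost_irrigation_fixed
}
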