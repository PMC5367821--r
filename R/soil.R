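# Soil classes and the soil-class raster ------------------------------------

# Reference ladder of six soil textures with per-event refill volumes
# (m3/ha): the amount of water a surge irrigation set delivers to bring the
# root zone back to saturation from the management-allowed depletion level.
# Coarse soils drain fast and hold little (small refill, frequent events);
# heavy soils buffer much more. Values are adapted to a 0.91 m root zone.
SOIL_REFERENCE <- data.frame(
  name = c("sand", "loamy_sand", "sandy_loam", "loam", "clay_loam", "clay"),
  refill_depth = c(245, 420, 600, 730, 850, 965),
  stringsAsFactors = FALSE
)

#' Define the soil classes of a farm
#'
#' Soil classes differ only in their ability to hold water: each class has a
#' `refill_depth`, the volume per unit area one irrigation event delivers to
#' re-saturate the root zone from the trigger level. Ids are consecutive
#' from 1 and ordered coarse (sand) to heavy (clay).
#'
#' @param n_classes number of classes, 1 to 6. The default 5 matches the
#'   case-study farm (sand through clay, skipping clay loam).
#' @param refill_depth optional numeric vector of per-event refill volumes
#'   (m3/ha), one per class; defaults are drawn from a six-texture ladder.
#' @param names optional character vector of class labels.
#' @return a data.frame with columns `id`, `name`, `refill_depth`.
#' @export
soil_classes <- function(n_classes = 5, refill_depth = NULL, names = NULL) {
  stopifnot(n_classes >= 1, n_classes <= 6)
  pick <- if (n_classes == 5) c(1L, 2L, 3L, 4L, 6L) else round(seq(1, 6, length.out = n_classes))
  out <- data.frame(
    id = seq_len(n_classes),
    name = if (is.null(names)) SOIL_REFERENCE$name[pick] else names,
    refill_depth = if (is.null(refill_depth)) SOIL_REFERENCE$refill_depth[pick] else refill_depth,
    stringsAsFactors = FALSE
  )
  if (any(out$refill_depth <= 0)) stop("refill_depth must be positive", call. = FALSE)
  out
}

#' Construct a soil grid
#'
#' A farm is an `M x N` raster of square land units, each labelled with one
#' soil-class id. Units are indexed row-major with row 1 at the north edge.
#'
#' @param cells integer matrix of soil-class ids (1-based, consecutive).
#' @param unit_area area of one land unit (ha); default is half an acre.
#' @param classes soil-class table as returned by [soil_classes()]; defaults
#'   to `soil_classes(max(cells))`.
#' @return an object of class `soil_grid`.
#' @export
soil_grid <- function(cells, unit_area = acres_to_ha(0.5), classes = NULL) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  if (any(is.na(cells))) stop("soil grid contains missing cells", call. = FALSE)
  J <- max(cells)
  if (min(cells) < 1L) stop("soil-class ids must be >= 1", call. = FALSE)
  if (is.null(classes)) classes <- soil_classes(J)
  if (J > nrow(classes)) stop("grid references soil id ", J, " but only ",
    nrow(classes), " classes are defined", call. = FALSE)
  if (!identical(classes$id, seq_len(nrow(classes)))) {
    stop("soil-class ids must be consecutive from 1", call. = FALSE)
  }
  stopifnot(is.numeric(unit_area), length(unit_area) == 1L, unit_area > 0)
  structure(
    list(cells = cells, unit_area = unit_area, classes = classes),
    class = "soil_grid"
  )
}

#' @export
print.soil_grid <- function(x, ...) {
  cat(sprintf(
    "Soil grid: %d x %d land units of %.4f ha (%d soil classes, %.2f ha total)\n",
    nrow(x$cells), ncol(x$cells), x$unit_area, nrow(x$classes),
    length(x$cells) * x$unit_area
  ))
  tab <- table(factor(x$cells, levels = x$classes$id))
  for (j in x$classes$id) {
    cat(sprintf("  %-12s %4d units\n", x$classes$name[j], tab[[j]]))
  }
  invisible(x)
}

#' Number of land units in a grid
#' @param grid a `soil_grid`.
#' @return integer count `M * N`.
#' @export
n_units <- function(grid) length(grid$cells)

# Row-major unit indexing: unit u of an M x N grid sits at
# row = (u - 1) %/% N + 1, col = (u - 1) %% N + 1.
unit_soil <- function(grid) as.integer(t(grid$cells))

#' Land-condition indicator matrix
#'
#' Returns the binary matrix `L` with `L[u, j] = 1` iff land unit `u` has
#' soil class `j`; every row sums to one. Units are numbered row-major.
#'
#' @param grid a `soil_grid`.
#' @return a `U x J` 0/1 matrix.
#' @export
soil_indicator <- function(grid) {
  j <- unit_soil(grid)
  J <- nrow(grid$classes)
  L <- matrix(0L, length(j), J)
  L[cbind(seq_along(j), j)] <- 1L
  L
}

#' Integrate a fine soil raster onto the land-unit grid by majority vote
#'
#' Soil surveys resolve finer than the land-unit grid; each land unit takes
#' the modal soil class of the `factor x factor` block of fine cells it
#' covers. Ties go to the lowest class id, deterministically.
#'
#' @param raster integer matrix of fine soil-class ids, dimensions divisible
#'   by `factor`.
#' @param factor integer block edge: one land unit covers `factor^2` fine
#'   cells.
#' @return integer matrix of land-unit soil ids with dimensions
#'   `dim(raster) / factor`.
#' @export
majority_vote_downsample <- function(raster, factor) {
  raster <- as.matrix(raster)
  storage.mode(raster) <- "integer"
  factor <- as.integer(factor)
  if (factor < 1L) stop("block factor must be a positive integer", call. = FALSE)
  if (nrow(raster) %% factor != 0L || ncol(raster) %% factor != 0L) {
    stop("raster dimensions ", nrow(raster), " x ", ncol(raster),
      " are not divisible by block factor ", factor, call. = FALSE)
  }
  M <- nrow(raster) %/% factor
  N <- ncol(raster) %/% factor
  out <- matrix(NA_integer_, M, N)
  for (i in seq_len(M)) {
    for (k in seq_len(N)) {
      block <- raster[
        ((i - 1L) * factor + 1L):(i * factor),
        ((k - 1L) * factor + 1L):(k * factor)
      ]
      counts <- tabulate(block)
      out[i, k] <- which.max(counts) # ties: lowest id wins
    }
  }
  out
}
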