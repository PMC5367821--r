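# Decision-unit tilings -----------------------------------------------------

#' Tile the land-unit grid into rectangular decision units
#'
#' A decision unit is a rectangle of contiguous land units that must share
#' one seed type and/or one irrigation frequency. Three regular structures
#' are supported: `"row"` (full-width horizontal strips), `"column"`
#' (full-height vertical strips), and `"square"` (a k x k grid of equal
#' blocks, `n_units = k^2`). Rectangles are stored 0-based and half-open,
#' with row 0 at the north edge.
#'
#' @param n_rows,n_cols grid dimensions (land units).
#' @param n_units number of decision units.
#' @param shape one of `"square"`, `"row"`, `"column"`.
#' @return an object of class `partition`: list with `n_rows`, `n_cols`,
#'   `shape`, `n_units`, and a data.frame `rectangles` with columns
#'   `row0`, `col0`, `height`, `width`.
#' @examples
#' make_partition(18, 18, 4, "square")  # four 9 x 9 blocks
#' @export
make_partition <- function(n_rows, n_cols, n_units, shape = c("square", "row", "column")) {
  shape <- match.arg(shape)
  stopifnot(n_rows >= 1, n_cols >= 1, n_units >= 1)
  if (shape == "row") {
    if (n_rows %% n_units != 0L) {
      stop("infeasible tiling: row structure needs n_units (", n_units,
        ") to divide the grid height (", n_rows, ")", call. = FALSE)
    }
    h <- n_rows %/% n_units
    rect <- data.frame(
      row0 = (seq_len(n_units) - 1L) * h, col0 = 0L,
      height = h, width = n_cols
    )
  } else if (shape == "column") {
    if (n_cols %% n_units != 0L) {
      stop("infeasible tiling: column structure needs n_units (", n_units,
        ") to divide the grid width (", n_cols, ")", call. = FALSE)
    }
    w <- n_cols %/% n_units
    rect <- data.frame(
      row0 = 0L, col0 = (seq_len(n_units) - 1L) * w,
      height = n_rows, width = w
    )
  } else {
    k <- round(sqrt(n_units))
    if (k * k != n_units) {
      stop("infeasible tiling: square structure needs n_units (", n_units,
        ") to be a perfect square", call. = FALSE)
    }
    if (n_rows %% k != 0L || n_cols %% k != 0L) {
      stop("infeasible tiling: square structure needs k = ", k,
        " to divide both grid dimensions (", n_rows, " x ", n_cols, ")",
        call. = FALSE)
    }
    h <- n_rows %/% k; w <- n_cols %/% k
    g <- expand.grid(br = seq_len(k) - 1L, bc = seq_len(k) - 1L)
    g <- g[order(g$br, g$bc), ]
    rect <- data.frame(row0 = g$br * h, col0 = g$bc * w, height = h, width = w)
  }
  new_partition(n_rows, n_cols, rect, shape)
}

#' Build a partition from explicit rectangles
#'
#' @param n_rows,n_cols grid dimensions.
#' @param rectangles data.frame with columns `row0`, `col0`, `height`,
#'   `width` (0-based, half-open). Must tile the grid exactly.
#' @param shape label stored on the partition; defaults to `"custom"`.
#' @return a `partition`.
#' @export
partition_from_rectangles <- function(n_rows, n_cols, rectangles, shape = "custom") {
  new_partition(n_rows, n_cols, rectangles, shape)
}

new_partition <- function(n_rows, n_cols, rectangles, shape) {
  req <- c("row0", "col0", "height", "width")
  stopifnot(all(req %in% names(rectangles)))
  rectangles <- as.data.frame(rectangles)[req]
  p <- structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      shape = shape, n_units = nrow(rectangles), rectangles = rectangles
    ),
    class = "partition"
  )
  # coverage / disjointness: every cell must fall in exactly one rectangle
  cover <- matrix(0L, n_rows, n_cols)
  for (v in seq_len(nrow(rectangles))) {
    r <- rectangles[v, ]
    if (r$row0 < 0 || r$col0 < 0 || r$height < 1 || r$width < 1 ||
        r$row0 + r$height > n_rows || r$col0 + r$width > n_cols) {
      stop("rectangle ", v, " lies outside the ", n_rows, " x ", n_cols,
        " grid", call. = FALSE)
    }
    rows <- (r$row0 + 1L):(r$row0 + r$height)
    cols <- (r$col0 + 1L):(r$col0 + r$width)
    cover[rows, cols] <- cover[rows, cols] + 1L
  }
  if (any(cover != 1L)) {
    stop("rectangles must tile the grid exactly (found ",
      sum(cover == 0L), " uncovered and ", sum(cover > 1L),
      " doubly covered cells)", call. = FALSE)
  }
  p
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition: %d decision units (%s) on a %d x %d grid\n",
    x$n_units, x$shape, x$n_rows, x$n_cols))
  invisible(x)
}

#' Decision-unit membership of every land unit
#'
#' @param partition a `partition`.
#' @return integer vector of length `n_rows * n_cols` (row-major unit
#'   order) giving the decision unit of each land unit.
#' @export
partition_membership <- function(partition) {
  mem <- matrix(NA_integer_, partition$n_rows, partition$n_cols)
  for (v in seq_len(partition$n_units)) {
    r <- partition$rectangles[v, ]
    mem[(r$row0 + 1L):(r$row0 + r$height), (r$col0 + 1L):(r$col0 + r$width)] <- v
  }
  as.integer(t(mem))
}

#' Test whether one tiling refines another
#'
#' `fine` refines `coarse` when every rectangle of `fine` lies entirely
#' inside one rectangle of `coarse`; decisions feasible under `coarse` are
#' then feasible under `fine`, so optimal profit can only improve.
#'
#' @param fine,coarse two `partition` objects on the same grid.
#' @return `TRUE` or `FALSE`.
#' @export
is_refinement <- function(fine, coarse) {
  if (fine$n_rows != coarse$n_rows || fine$n_cols != coarse$n_cols) {
    stop("partitions live on different grids", call. = FALSE)
  }
  mf <- partition_membership(fine)
  mc <- partition_membership(coarse)
  all(tapply(mc, mf, function(x) length(unique(x)) == 1L))
}

#' The sixteen management-scale scenarios of the case study
#'
#' The scenario ladder varies the number and shape of decision units on the
#' 18 x 18 case-study grid, from one whole-farm unit up to 324 single-unit
#' squares. (Two- and three-block square tilings are impossible on an
#' 18 x 18 grid and are correspondingly absent.)
#'
#' @return data.frame with columns `scenario`, `n_units`, `shape`.
#' @export
scale_scenarios <- function() {
  data.frame(
    scenario = 1:16,
    n_units = c(1L, 2L, 2L, 3L, 3L, 4L, 6L, 6L, 9L, 9L, 9L, 18L, 18L, 36L, 81L, 324L),
    shape = c(
      "square", "row", "column", "row", "column", "square", "row", "column",
      "row", "column", "square", "row", "column", "square", "square", "square"
    ),
    stringsAsFactors = FALSE
  )
}
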