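test_that("regular tilings are built exactly or refused with the reason", {
  whole <- make_partition(18, 18, 1, "square")
  expect_identical(whole$n_units, 1L)
  expect_identical(as.integer(whole$rectangles[1, ]), c(0L, 0L, 18L, 18L))

  four <- make_partition(18, 18, 4, "square")
  expect_identical(four$n_units, 4L)
  expect_true(all(four$rectangles$height == 9L & four$rectangles$width == 9L))

  rows <- make_partition(18, 18, 6, "row")
  expect_true(all(rows$rectangles$width == 18L & rows$rectangles$height == 3L))

  expect_error(make_partition(18, 18, 5, "row"), "divide the grid height")
  expect_error(make_partition(18, 18, 8, "square"), "perfect square")
  expect_error(make_partition(18, 18, 25, "square"), "divide both grid dimensions")
})

test_that("membership covers every land unit exactly once", {
  specs <- list(c(1, "square"), c(4, "square"), c(9, "square"), c(324, "square"),
    c(2, "row"), c(18, "row"), c(3, "column"), c(6, "column"))
  for (sp in specs) {
    p <- make_partition(18, 18, as.integer(sp[1]), sp[2])
    mem <- partition_membership(p)
    expect_false(anyNA(mem))
    expect_identical(length(mem), 324L)
    sizes <- tabulate(mem, p$n_units)
    expect_identical(sum(sizes), 324L)
    expect_true(all(sizes == 324L / p$n_units))
  }
  expect_error(
    partition_from_rectangles(4, 4, data.frame(row0 = 0, col0 = 0, height = 4, width = 3)),
    "tile the grid exactly"
  )
  expect_error(
    partition_from_rectangles(2, 2, data.frame(
      row0 = c(0, 0), col0 = c(0, 0), height = c(2, 2), width = c(2, 2))),
    "doubly covered"
  )
})

test_that("refinement captures nesting of tilings", {
  singles <- make_partition(18, 18, 324, "square")
  for (sp in list(c(1, "square"), c(4, "square"), c(6, "row"), c(9, "column"))) {
    coarse <- make_partition(18, 18, as.integer(sp[1]), sp[2])
    expect_true(is_refinement(singles, coarse))
  }
  expect_false(is_refinement(make_partition(18, 18, 2, "row"),
    make_partition(18, 18, 2, "column")))
  expect_true(is_refinement(make_partition(18, 18, 36, "square"),
    make_partition(18, 18, 4, "square")))
  expect_error(
    is_refinement(make_partition(6, 6, 4, "square"), make_partition(18, 18, 4, "square")),
    "different grids"
  )
})

test_that("refinement is a partial order on the square ladder", {
  ladder <- lapply(c(1, 4, 9, 36, 81, 324), function(n) {
    make_partition(18, 18, n, "square")
  })
  for (a in seq_along(ladder)) {
    expect_true(is_refinement(ladder[[a]], ladder[[a]])) # reflexive
    for (b in seq_along(ladder)) {
      for (cc in seq_along(ladder)) {
        if (is_refinement(ladder[[a]], ladder[[b]]) &&
            is_refinement(ladder[[b]], ladder[[cc]])) {
          expect_true(is_refinement(ladder[[a]], ladder[[cc]])) # transitive
        }
      }
      if (a != b && is_refinement(ladder[[a]], ladder[[b]])) {
        expect_false(is_refinement(ladder[[b]], ladder[[a]])) # antisymmetric
      }
    }
  }
  # 36 squares nest in 4 squares but not conversely; rows and columns cross
  expect_false(is_refinement(make_partition(18, 18, 4, "square"),
    make_partition(18, 18, 36, "square")))
})

test_that("the scenario ladder lists the sixteen case-study tilings", {
  sc <- scale_scenarios()
  expect_identical(nrow(sc), 16L)
  expect_identical(sc$n_units[1], 1L)
  expect_identical(sc$shape[1], "square")
  expect_identical(sc$n_units[16], 324L)
  expect_identical(sc$shape[16], "square")
  expect_identical(sum(sc$shape == "square"), 6L)
  for (k in seq_len(16)) {
    expect_silent(make_partition(18, 18, sc$n_units[k], sc$shape[k]))
  }
})
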