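toy_grid <- function(dims, origin = c(0, 0, 0), spacing = 2) {
  structure(list(origin = origin, spacing = spacing,
                 dims = as.integer(dims)), class = "pae_grid")
}

toy_desc <- function(map) {
  structure(list(map = map), class = "pae_descriptors")
}

test_that("stdev*coefficient values land on the right grid points", {
  grid <- toy_grid(c(3, 2, 1))            # 6 points
  map <- data.frame(field = "CoMFA_S", point = c(2L, 5L), column = 1:2)
  m <- fake_pls(coef = c(0.5, -1), x_sd = c(2, 3))
  cf <- stdev_coeff_field(m, toy_desc(map), grid, "CoMFA_S")
  expect_equal(cf$values, c(0, 1, 0, 0, -3, 0))
  # masked points carry exactly 0
  expect_identical(cf$values[c(1, 3, 4, 6)], rep(0, 4))

  # doubling a column sd doubles its contour value
  m2 <- fake_pls(coef = c(0.5, -1), x_sd = c(4, 3))
  cf2 <- stdev_coeff_field(m2, toy_desc(map), grid, "CoMFA_S")
  expect_equal(cf2$values[2], 2 * cf$values[2])

  zero <- fake_pls(coef = c(0, 0), x_sd = c(2, 3))
  expect_true(all(stdev_coeff_field(zero, toy_desc(map), grid,
                                    "CoMFA_S")$values == 0))
  expect_error(stdev_coeff_field(m, toy_desc(map), grid, "CoMSIA_H"),
               "not present")
})

test_that("region extraction finds a planted bump and respects scaling", {
  dims <- c(7, 7, 7)
  grid <- toy_grid(dims)
  pts <- grid_points(grid)
  apex <- c(6, 6, 6)
  vals <- exp(-0.15 * rowSums(sweep(pts, 2, apex)^2)) -
          0.5 * exp(-0.15 * rowSums(sweep(pts, 2, c(2, 2, 2))^2))
  cf <- structure(list(kind = "CoMSIA_H", grid = grid, values = vals),
                  class = "pae_contour_field")
  reg <- extract_regions(cf)
  fav <- reg$regions[reg$regions$sign == "favorable", ]
  expect_equal(nrow(fav), 1L)
  apex_idx <- which.max(vals)
  expect_equal(reg$labels[apex_idx], fav$id)

  # positive global scaling leaves the labeling unchanged
  cf10 <- cf
  cf10$values <- cf$values * 10
  reg10 <- extract_regions(cf10)
  expect_identical(reg10$labels, reg$labels)

  # every labeled point carries a nonzero (retained) field value
  expect_true(all(cf$values[reg$labels > 0] != 0))
})

test_that("mirror-symmetric fields give mirror-symmetric regions", {
  grid <- toy_grid(c(6, 3, 3))
  pts <- grid_points(grid)
  # antisymmetric in x about the box center (x = 5)
  vals <- (pts[, 1] - 5) * exp(-0.1 * (pts[, 2] - 2)^2)
  cf <- structure(list(kind = "CoMFA_E", grid = grid, values = vals),
                  class = "pae_contour_field")
  reg <- extract_regions(cf)
  fav_ids <- reg$regions$id[reg$regions$sign == "favorable"]
  unf_ids <- reg$regions$id[reg$regions$sign == "unfavorable"]
  fav_pts <- pts[reg$labels %in% fav_ids, , drop = FALSE]
  unf_pts <- pts[reg$labels %in% unf_ids, , drop = FALSE]
  mirrored <- cbind(10 - unf_pts[, 1], unf_pts[, 2], unf_pts[, 3])
  expect_setequal(apply(fav_pts, 1, paste, collapse = ","),
                  apply(mirrored, 1, paste, collapse = ","))
})

test_that("constant fields yield a warning and no regions", {
  grid <- toy_grid(c(3, 3, 3))
  cf <- structure(list(kind = "CoMFA_S", grid = grid,
                       values = rep(2, 27)), class = "pae_contour_field")
  expect_warning(reg <- extract_regions(cf), "constant")
  expect_equal(nrow(reg$regions), 0L)
})

test_that("region summaries export as JSON", {
  grid <- toy_grid(c(5, 5, 5))
  pts <- grid_points(grid)
  vals <- exp(-0.2 * rowSums(sweep(pts, 2, c(4, 4, 4))^2))
  cf <- structure(list(kind = "CoMSIA_S", grid = grid, values = vals),
                  class = "pae_contour_field")
  reg <- extract_regions(cf)
  path <- withr::local_tempfile(fileext = ".json")
  write_regions_json(reg, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(nrow(back$regions), nrow(reg$regions))
  expect_true(all(c("id", "sign", "n_points") %in% names(back$regions)))
})
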