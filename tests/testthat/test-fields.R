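test_that("grid construction snaps outward and contains every atom", {
  atom <- toy_mol(rbind(c(0, 0, 0)))
  g <- build_grid(atom, spacing = 2, margin = 4)
  expect_equal(g$dims, c(5L, 5L, 5L))
  expect_equal(g$origin, c(-4, -4, -4))

  # enlarging the margin never removes grid points
  g6 <- build_grid(atom, spacing = 2, margin = 6)
  pts4 <- apply(grid_points(g), 1, paste, collapse = ",")
  pts6 <- apply(grid_points(g6), 1, paste, collapse = ",")
  expect_true(all(pts4 %in% pts6))

  mols <- pae_test_ensemble()[c("DMP", "DEHP", "DIDP")]
  gg <- build_grid(mols, spacing = 2, margin = 4)
  xyz <- do.call(rbind, lapply(mols, function(m)
    as.matrix(m$atoms[, c("x", "y", "z")])))
  lo <- gg$origin
  hi <- gg$origin + gg$spacing * (gg$dims - 1L)
  expect_true(all(sweep(xyz, 2, lo, ">") & sweep(xyz, 2, hi, "<")))
  expect_error(build_grid(list()), "at least one")
})

test_that("CoMFA fields: decay, clipping and neutral-atom electrostatics", {
  atom <- toy_mol(rbind(c(0, 0, 0)), charge = 0)
  far <- structure(list(origin = c(50, 0, 0), spacing = 2,
                        dims = c(2L, 2L, 2L)), class = "pae_grid")
  f <- comfa_fields(atom, far)
  expect_true(all(abs(f$steric) < 1e-4))
  expect_true(all(f$electrostatic == 0))

  near <- structure(list(origin = c(0, 0, 0), spacing = 2,
                         dims = c(1L, 1L, 1L)), class = "pae_grid")
  g <- comfa_fields(atom, near)      # probe on top of the atom
  expect_identical(g$steric, 30)     # clipped exactly, never infinite
  expect_true(g$excluded)
})

test_that("CoMFA matches a hand-summed Lennard-Jones/Coulomb oracle", {
  two <- toy_mol(rbind(c(0, 0, 0), c(1.5, 0, 0)),
                 elements = c("C", "O"), charge = c(0.2, -0.2))
  pt <- c(3.5, 1, 0)
  grid <- structure(list(origin = pt, spacing = 2, dims = c(1L, 1L, 1L)),
                    class = "pae_grid")
  probe <- probe_spec()
  f <- comfa_fields(two, grid, probe)

  r <- c(sqrt(sum((pt - c(0, 0, 0))^2)), sqrt(sum((pt - c(1.5, 0, 0))^2)))
  Rij <- c(1.70, 1.52) + probe$steric_r
  epsij <- sqrt(c(0.107, 0.116) * probe$steric_eps)
  lj <- sum(epsij * ((Rij / r)^12 - 2 * (Rij / r)^6))
  coulomb <- sum(332.0 * c(0.2, -0.2) / r^2)
  expect_equal(f$steric, lj, tolerance = 1e-12)
  expect_equal(f$electrostatic, coulomb, tolerance = 1e-12)
})

test_that("CoMSIA indices are Gaussian overlaps with the right limits", {
  atom <- toy_mol(rbind(c(0, 0, 0)), charge = 0.3, hydro = 0.5,
                  acceptor = TRUE)
  ongrid <- structure(list(origin = c(0, 0, 0), spacing = 2,
                           dims = c(1L, 1L, 1L)), class = "pae_grid")
  f <- comsia_fields(atom, ongrid)
  expect_equal(f$E, -0.3)                 # Gaussian = 1 at the atom
  expect_equal(f$H, -0.5)
  expect_equal(f$A, -1)
  expect_equal(f$S, -1.7^3)               # vdW-volume weight

  faraway <- structure(list(origin = c(40, 0, 0), spacing = 2,
                            dims = c(1L, 1L, 1L)), class = "pae_grid")
  expect_true(all(abs(unlist(comsia_fields(atom, faraway))) < 1e-12))

  # two-atom hand oracle at alpha = 0.3
  two <- toy_mol(rbind(c(0, 0, 0), c(2, 0, 0)), charge = c(0.1, -0.2),
                 hydro = c(0.4, -0.1))
  pt <- c(1, 1.5, 0)
  grid1 <- structure(list(origin = pt, spacing = 2, dims = c(1L, 1L, 1L)),
                     class = "pae_grid")
  f2 <- comsia_fields(two, grid1)
  d2 <- c(sum((pt - c(0, 0, 0))^2), sum((pt - c(2, 0, 0))^2))
  expect_equal(f2$H, -sum(c(0.4, -0.1) * exp(-0.3 * d2)), tolerance = 1e-12)
  expect_equal(f2$E, -sum(c(0.1, -0.2) * exp(-0.3 * d2)), tolerance = 1e-12)

  mol <- toy_mol(rbind(c(0, 0, 0)))
  mol$atoms$hydro <- NULL
  expect_error(comsia_fields(mol, ongrid), "annotations")
})

test_that("CoMSIA fields are bounded and cutoff-free", {
  mol <- pae_test_mol("DEHP")
  grid <- build_grid(list(mol), spacing = 2, margin = 4)
  f <- comsia_fields(mol, grid)
  expect_true(all(is.finite(unlist(f))))
  for (k in c("E", "H", "D", "A")) {
    w <- switch(k, E = mol$atoms$charge, H = mol$atoms$hydro,
                D = as.numeric(mol$atoms$donor),
                A = as.numeric(mol$atoms$acceptor))
    expect_lte(max(abs(f[[k]])), sum(abs(w)) + 1e-12)
  }
})

test_that("fields are invariant under joint translation", {
  mol <- pae_test_mol("DMP")
  grid <- build_grid(list(mol), spacing = 2, margin = 4)
  shift <- c(3.123, -1.5, 0.77)
  mol2 <- mol
  mol2$atoms[, c("x", "y", "z")] <- mol2$atoms[, c("x", "y", "z")] +
    rep(shift, each = nrow(mol2$atoms))
  grid2 <- grid
  grid2$origin <- grid$origin + shift
  a <- comfa_fields(mol, grid)
  b <- comfa_fields(mol2, grid2)
  expect_equal(a$steric, b$steric, tolerance = 1e-10)
  expect_equal(a$electrostatic_raw, b$electrostatic_raw, tolerance = 1e-10)
  ca <- comsia_fields(mol, grid)
  cb <- comsia_fields(mol2, grid2)
  expect_equal(ca, cb, tolerance = 1e-10)
})

test_that("column filtering masks by cross-compound standard deviation", {
  vals <- rbind(c(1, 0, 5, 2), c(1, 0.01, 6, 2), c(1, -0.01, 7, 2))
  blk <- paeqsar:::new_field_block("CoMSIA_H", vals)
  f <- filter_columns(blk, min_sigma = 0.5)
  expect_equal(which(f$mask), 3L)          # only the varying column
  expect_equal(which(filter_columns(blk, 0)$mask), 1:4)
  expect_error(filter_columns(blk, 1e6), "every column")

  const <- paeqsar:::new_field_block("CoMFA_S", rbind(c(1, 3), c(1, 4),
                                                      c(1, 5)))
  expect_false(filter_columns(const, min_sigma = 0.5)$mask[1])
})

test_that("descriptor assembly block-scales and round-trips its map", {
  set.seed(11)
  v1 <- matrix(rnorm(12, sd = 4), 3, dimnames = list(c("a", "b", "c")))
  v2 <- matrix(rnorm(12, sd = 0.1), 3, dimnames = list(c("a", "b", "c")))
  b1 <- filter_columns(paeqsar:::new_field_block("CoMFA_S", v1), 0)
  b2 <- filter_columns(paeqsar:::new_field_block("CoMFA_E", v2), 0)

  one <- assemble_descriptors(list(b1))
  expect_equal(unname(one$X), unname(v1 / sd(as.vector(v1))))

  twin <- assemble_descriptors(list(
    filter_columns(paeqsar:::new_field_block("CoMFA_S", v1), 0),
    filter_columns(paeqsar:::new_field_block("CoMFA_E", v1), 0)))
  expect_equal(unname(twin$X[, 1:4]), unname(twin$X[, 5:8]))

  both <- assemble_descriptors(list(b1, b2))
  expect_equal(nrow(both$map), ncol(both$X))
  # bijection: every retained (field, point) appears exactly once
  expect_false(anyDuplicated(both$map[c("field", "point")]) > 0)
  for (j in seq_len(nrow(both$map))) {
    src <- if (both$map$field[j] == "CoMFA_S") v1 else v2
    sc <- both$scales[both$map$field[j]]
    expect_equal(unname(both$X[, both$map$column[j]]),
                 unname(src[, both$map$point[j]] / sc))
  }

  bad <- paeqsar:::new_field_block("CoMFA_E",
                                   v2[c(3, 1, 2), ])
  rownames(bad$values) <- c("c", "a", "b")
  expect_error(assemble_descriptors(list(b1, filter_columns(bad, 0))),
               "compound order")
})

test_that("grid maps round-trip through the plain-text format", {
  g <- structure(list(origin = c(-4, -2, 0), spacing = 2,
                      dims = c(3L, 2L, 2L)), class = "pae_grid")
  vals <- rnorm(12)
  path <- withr::local_tempfile(fileext = ".txt")
  write_grid_map(vals, g, path)
  back <- read_grid_map(path)
  expect_equal(back$grid$origin, g$origin)
  expect_equal(back$grid$dims, g$dims)
  expect_equal(back$values, vals, tolerance = 1e-9)
})
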