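test_that("unit-cell matrix follows the monoclinic convention", {
  cell <- study_cell()
  m <- unit_cell_matrix(cell)

  ## a along x
  expect_equal(frac_to_cart(c(1, 0, 0), cell)[1, ], c(65.30, 0, 0))
  ## b along y
  expect_equal(frac_to_cart(c(0, 1, 0), cell)[1, ], c(0, 39.45, 0))
  ## c in the x-z plane: (c cos(beta), 0, c sin(beta)), evaluated directly
  cc <- 39.01 * c(cospi(117.54 / 180), 0, sinpi(117.54 / 180))
  expect_equal(frac_to_cart(c(0, 0, 1), cell)[1, ], cc, tolerance = 1e-12)
  expect_equal(cc[1], -18.037, tolerance = 1e-3)
  expect_equal(cc[3], 34.590, tolerance = 1e-3)
  ## linearity
  expect_equal(frac_to_cart(c(0.5, 0.5, 0), cell)[1, ], c(32.65, 19.725, 0))
  expect_gt(det(m), 0)
})

test_that("degenerate and invalid cells are rejected", {
  expect_error(unit_cell(0, 10, 10), "positive")
  expect_error(unit_cell(10, 10, 10, beta = 180), "angles")
  ## alpha + gamma conspiring to a flat cell
  expect_error(unit_cell(10, 10, 10, alpha = 90, beta = 179.999,
                         gamma = 90), "degenerate")
})

test_that("fractional/Cartesian round trip is exact to 1e-10", {
  cell <- unit_cell(30, 40, 50, alpha = 85, beta = 110, gamma = 95)
  set.seed(42)
  x <- matrix(runif(60, -2, 2), ncol = 3)
  back <- cart_to_frac(frac_to_cart(x, cell), cell)
  expect_lt(max(abs(back - x)), 1e-10)
})

test_that("C121 carries four operators with group closure", {
  ops <- symmetry_operators("C121")
  expect_length(ops, 4)
  ## two-fold axis flips x and z
  expect_equal(apply_op <- as.numeric(
    ops[[2]]$rotation %*% c(0.1, 0.2, 0.3) + ops[[2]]$translation),
    c(-0.1, 0.2, -0.3))

  ## closure: every product of two operators, reduced mod 1, is in the set
  in_set <- function(r, t) {
    any(vapply(ops, function(o) {
      all(o$rotation == r) && all(abs((t - o$translation) %% 1) < 1e-12)
    }, logical(1)))
  }
  for (o1 in ops) {
    for (o2 in ops) {
      r12 <- o1$rotation %*% o2$rotation
      t12 <- (as.numeric(o1$rotation %*% o2$translation) +
                o1$translation) %% 1
      expect_true(in_set(r12, t12))
    }
  }

  ## a general-position point has 4 distinct images modulo the lattice
  p <- c(0.137, 0.211, 0.317)
  imgs <- t(vapply(ops, function(o)
    as.numeric(o$rotation %*% p + o$translation) %% 1, numeric(3)))
  expect_equal(nrow(unique(round(imgs, 9))), 4)

  expect_error(symmetry_operators("P212121"), "unknown space group")
  expect_length(symmetry_operators("P1"), 1)
})

test_that("supercell construction yields 4 chains per cell, conserving atoms", {
  cell <- study_cell()
  tpl <- toy_chain(6)
  sc3 <- build_supercell(tpl$coords, cell, c(3, 3, 3), atoms = tpl$atoms)
  expect_equal(dim(sc3$coords)[3], 108)
  expect_equal(nrow(sc3$sites), 108)
  expect_equal(dim(sc3$coords)[1], nrow(tpl$coords))

  sc1 <- build_supercell(tpl$coords, cell, c(1, 1, 1), atoms = tpl$atoms)
  expect_equal(dim(sc1$coords)[3], 4)

  ## every chain is an isometric image of the template
  d0 <- dist(tpl$coords)
  for (ch in c(1, 2, 57, 108)) {
    expect_equal(as.numeric(dist(sc3$coords[, , ch])), as.numeric(d0),
                 tolerance = 1e-9)
  }
  ## ideal site centres of mass are distinct
  expect_equal(nrow(dplyr::distinct(
    round(sc3$sites[c("com_x", "com_y", "com_z")], 6))), 108)

  expect_error(build_supercell(tpl$coords, cell, c(0, 3, 3)), "positive")
})

test_that("inverse lattice transform recovers displacements exactly", {
  cell <- study_cell()
  tpl <- toy_chain(6)
  sc <- build_supercell(tpl$coords, cell, c(2, 2, 2), atoms = tpl$atoms)
  nc <- dim(sc$coords)[3]
  na <- dim(sc$coords)[1]

  ## undistorted lattice: all displacements at the origin
  ens0 <- trajectory_ensemble(array(sc$coords, c(na, 3, 1, nc)), tpl$atoms)
  d0 <- inverse_lattice_transform(ens0, sc$sites, cell)
  expect_lt(max(d0$dmag), 1e-9)

  ## one chain rigidly translated by (1,2,3): magnitude sqrt(14), rest 0
  co <- array(sc$coords, c(na, 3, 1, nc))
  co[, , 1, 7] <- sweep(co[, , 1, 7], 2, c(1, 2, 3), "+")
  d1 <- inverse_lattice_transform(
    trajectory_ensemble(co, tpl$atoms), sc$sites, cell)
  expect_equal(d1$dmag[d1$chain == 7], sqrt(14), tolerance = 1e-9)
  expect_lt(max(d1$dmag[d1$chain != 7]), 1e-9)

  ## a two-fold-generated chain displaced by t maps to the operator
  ## inverse image of t
  ops <- symmetry_operators("C121")
  m <- unit_cell_matrix(cell)
  two_fold <- which(sc$sites$operator == 2)[1]
  t_lab <- c(0.5, -1.2, 2.0)
  co2 <- array(sc$coords, c(na, 3, 1, nc))
  co2[, , 1, two_fold] <- sweep(co2[, , 1, two_fold], 2, t_lab, "+")
  d2 <- inverse_lattice_transform(
    trajectory_ensemble(co2, tpl$atoms), sc$sites, cell)
  r_cart <- m %*% solve(ops[[2]]$rotation) %*% solve(m)
  expected <- as.numeric(r_cart %*% t_lab)
  got <- unlist(d2[d2$chain == two_fold, c("dx", "dy", "dz")])
  expect_equal(unname(got), expected, tolerance = 1e-9)
  ## the inverse map is an isometry
  expect_equal(sqrt(sum(expected^2)), sqrt(sum(t_lab^2)), tolerance = 1e-9)

  expect_error(inverse_lattice_transform(ens0, sc$sites[1:3, ], cell),
               "mismatch")
})

test_that("disorder amplitude matches the Maxwell mean and handles edge cases", {
  ## all-zero displacements
  z <- tibble::tibble(dmag = rep(0, 10))
  expect_equal(disorder_amplitude(z)$amplitude, 0)
  expect_error(disorder_amplitude(z[0, ]), "empty")

  ## Monte-Carlo oracle: per-axis sigma = 1 gives mean 2 sqrt(2/pi)
  set.seed(11)
  v <- matrix(rnorm(3e4), ncol = 3)
  mc <- tibble::tibble(dmag = sqrt(rowSums(v^2)),
                       replica = rep(1:2, each = 5e3))
  amp <- disorder_amplitude(mc)
  expect_rel_equal(amp$amplitude, 2 * sqrt(2 / pi), 0.02)
  expect_equal(amp$n_replicas, 2)
  expect_false(is.na(amp$sd))
})

test_that("disorder amplitude is invariant under a global rigid translation", {
  cell <- study_cell()
  tpl <- toy_chain(6)
  spec <- synthetic_spec(template = tpl, cell = cell, n_cells = c(1, 1, 1),
                         n_frames = 10, sigma_rb = 0.7, sigma_int = 0.2,
                         ell = 0, loop = NULL, seed = 9)
  ens <- synth_crystal_trajectory(spec)
  a1 <- disorder_amplitude(
    inverse_lattice_transform(ens, attr(ens, "sites"), cell))$amplitude

  ## translate the template (hence reference and every chain) globally
  tpl2 <- tpl
  tpl2$coords <- sweep(tpl$coords, 2, c(10, -5, 3), "+")
  spec2 <- synthetic_spec(template = tpl2, cell = cell, n_cells = c(1, 1, 1),
                          n_frames = 10, sigma_rb = 0.7, sigma_int = 0.2,
                          ell = 0, loop = NULL, seed = 9)
  ens2 <- synth_crystal_trajectory(spec2)
  a2 <- disorder_amplitude(
    inverse_lattice_transform(ens2, attr(ens2, "sites"), cell))$amplitude
  expect_equal(a1, a2, tolerance = 1e-9)
})
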