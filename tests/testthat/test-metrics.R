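test_that("Kabsch superposition recovers constructed transforms", {
  set.seed(1)
  x <- matrix(rnorm(45), ncol = 3)

  ## identity
  fit0 <- kabsch_superpose(x, x)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_lt(fit0$rmsd, 1e-12)

  ## construct-then-recover for several random rotations/translations
  for (s in 1:5) {
    r0 <- random_rotation(s)
    y <- x %*% t(r0) + matrix(rep(c(3, -1, 2) * s, each = nrow(x)), ncol = 3)
    fit <- kabsch_superpose(x, y)
    expect_lt(max(abs(fit$rotation - r0)), 1e-8)
    expect_lt(fit$rmsd, 1e-10)
  }

  ## mirror image: rotation stays proper, RMSD nonzero
  y_mirror <- x %*% diag(c(-1, 1, 1))
  fitm <- kabsch_superpose(x, y_mirror)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-10)
  expect_gt(fitm$rmsd, 0.1)

  ## degenerate selections
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "3 atoms")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("deviation metrics vanish for rigid motion and localize a shift", {
  tpl <- toy_chain(50, seed = 5)
  na <- nrow(tpl$coords)

  ## whole trajectory rigidly moved: zero RMSD after superposition
  r0 <- random_rotation(3)
  co <- array(NA_real_, c(na, 3, 3, 1))
  for (f in 1:3) co[, , f, 1] <- tpl$coords %*% t(r0) + 5 * f
  ens <- trajectory_ensemble(co, tpl$atoms)
  r <- deviation_metrics(ens, tpl$coords, "rmsd_time", "heavy")
  expect_lt(max(r$rmsd_mean), 1e-9)
  expect_true(!is.null(attr(r, "trail_mean")))

  ## identical ensemble: all-zero MSD
  ens0 <- static_ensemble(tpl, n_frames = 2)
  msd0 <- deviation_metrics(ens0, tpl$coords, "msd_residue", "calpha")
  expect_lt(max(msd0$msd), 1e-18)

  ## one residue displaced by d in half the frames: MSD ~ d^2 / 2 there
  nf <- 10; d <- 2
  co2 <- array(rep(tpl$coords, nf), c(na, 3, nf, 1))
  ca25 <- which(tpl$atoms$residue_index == 25 & tpl$atoms$atom_name == "CA")
  for (f in 1:5) co2[ca25, 1, f, 1] <- co2[ca25, 1, f, 1] + d
  msd <- deviation_metrics(trajectory_ensemble(co2, tpl$atoms),
                           tpl$coords, "msd_residue", "calpha")
  expect_rel_equal(msd$msd[msd$residue == 25], d^2 / 2, 0.1)
  expect_lt(max(msd$msd[msd$residue != 25]), 0.05 * d^2 / 2)

  expect_error(deviation_metrics(ens, tpl$coords, "bogus"), "arg")
})

test_that("mean structure converges and is symmetric-pair exact", {
  tpl <- toy_chain(30, seed = 2)
  na <- nrow(tpl$coords)

  ## identical frames: converges immediately to that structure
  ens0 <- static_ensemble(tpl, n_frames = 3)
  ms0 <- mean_structure(ens0)
  expect_equal(ms0$coords, tpl$coords, tolerance = 1e-12)
  expect_equal(ms0$iterations, 1)

  ## pre-aligned symmetric pair: mean equals the reference
  set.seed(7)
  delta <- matrix(rnorm(na * 3, 0, 0.01), na)
  co <- array(c(tpl$coords + delta, tpl$coords - delta), c(na, 3, 2, 1))
  ms <- mean_structure(trajectory_ensemble(co, tpl$atoms), ref = tpl$coords)
  expect_lt(max(abs(ms$coords - tpl$coords)), 5e-3)
  expect_lt(attr(ms, "rmsd_to_ref"), 5e-3)

  expect_error(mean_structure(static_ensemble(tpl, n_frames = 1)),
               "at least 2")
})

test_that("native-contact Q behaves per definition and monotonically", {
  tpl <- toy_chain(40, seed = 3)
  contacts <- native_contacts(tpl$coords, tpl$atoms)
  expect_gt(nrow(contacts), 10)
  ## pairs obey the sequence-separation and distance rules
  sep <- abs(tpl$atoms$residue_index[contacts$atom_i] -
               tpl$atoms$residue_index[contacts$atom_j])
  expect_true(all(sep >= 4))
  expect_true(all(contacts$ref_dist < 4.5))

  expect_equal(native_contacts_q(tpl$coords, contacts), 1)

  set.seed(8)
  scrambled <- tpl$coords + matrix(rnorm(length(tpl$coords), 0, 10),
                                   ncol = 3)
  expect_lt(native_contacts_q(scrambled, contacts), 0.1)
  expect_equal(native_contacts_q(scrambled, contacts, Inf), 1)

  ## monotone non-increasing as the tolerance tightens
  tols <- c(2, 1.5, 1.2, 1.05, 1.0, 0.9)
  qs <- vapply(tols, function(tf)
    native_contacts_q(scrambled, contacts, tf), numeric(1))
  expect_true(all(diff(qs) <= 1e-12))

  expect_error(native_contacts_q(tpl$coords, contacts[0, ]), "empty")
})

test_that("B-factors follow B = (8 pi^2 / 3) RMSF^2 and mode ordering", {
  ## static ensemble: zero everywhere
  tpl <- toy_chain(20, seed = 1)
  bf0 <- bfactors(static_ensemble(tpl, n_frames = 3), "lattice",
                  ref = tpl$coords)
  expect_lt(max(bf0$b), 1e-18)
  expect_error(bfactors(static_ensemble(tpl, n_frames = 1), "chain"),
               "2 frames")

  ## isotropic per-coordinate sigma = 1: B -> 8 pi^2 (sampling oracle;
  ## superposition removes 6 of 3N dof, negligible at N = 500)
  set.seed(4)
  na <- 500; nf <- 300
  base <- matrix(rnorm(na * 3, 0, 30), na)
  co <- array(rnorm(na * 3 * nf), c(na, 3, nf, 1)) +
    array(rep(base, nf), c(na, 3, nf, 1))
  at <- tibble::tibble(atom_name = "CA", residue_index = seq_len(na),
                       residue_name = "ALA")
  bf1 <- bfactors(trajectory_ensemble(co, at), "lattice", ref = base)
  expect_rel_equal(mean(bf1$b), 8 * pi^2, 0.05)
})

test_that("covariance diagnostics: degenerate noise flagged, diagonal identity", {
  tpl <- toy_chain(25, seed = 6)
  spec <- synthetic_spec(template = tpl, n_cells = c(1, 1, 1),
                         space_group = "P1", n_frames = 150,
                         sigma_rb = 0, sigma_int = 0.4, ell = 11,
                         loop = NULL, seed = 2)
  ens <- synth_crystal_trajectory(spec)
  cv <- covariance_analysis(ens)
  ## covariance matrix is symmetric
  expect_equal(cv$C, t(cv$C), tolerance = 1e-12)
  ## diagonal equals per-atom RMSF^2: B_chain = (8 pi^2 / 3) diag(C)
  bc <- bfactors(ens, "chain", selection = "calpha")
  expect_equal(bc$b, (8 * pi^2 / 3) * diag(cv$C), tolerance = 1e-6)

  ## independent per-atom noise: off-diagonal bins near zero -> degenerate
  spec0 <- synthetic_spec(template = tpl, n_cells = c(1, 1, 1),
                          space_group = "P1", n_frames = 150,
                          sigma_rb = 0, sigma_int = 0.4, ell = 0,
                          loop = NULL, seed = 2)
  cv0 <- covariance_analysis(synth_crystal_trajectory(spec0))
  expect_true(cv0$degenerate)
})

test_that("covariance decay length is recovered from a known kernel", {
  tpl <- toy_chain(60, seed = 2)
  spec <- synthetic_spec(template = tpl, n_cells = c(1, 1, 1),
                         space_group = "P1", n_frames = 400,
                         sigma_rb = 0.5, sigma_int = 0.5, ell = 11,
                         loop = NULL, seed = 7)
  cv <- covariance_analysis(synth_crystal_trajectory(spec))
  expect_false(cv$degenerate)
  expect_rel_equal(cv$decay_length, 11, 0.15)
  ## the naive fit underestimates because superposition removes rigid
  ## modes; the projection-aware fit corrects this known bias
  expect_lt(cv$naive$decay_length, cv$decay_length)
})

test_that("equilibration verdicts follow the two conditions", {
  ## stationary replicas with equal means: pass
  s_ok <- synth_observable_series("plateau", seed = 2)
  r_ok <- equilibration_check(s_ok)
  expect_true(r_ok$equilibrated)

  ## monotone drift: plateau condition fails
  s_drift <- synth_observable_series("drift", drift_slope = 0.02, seed = 2)
  r_drift <- equilibration_check(s_drift)
  expect_false(r_drift$condition_plateau)

  ## offset replicas (10x their SE): agreement condition fails
  s_off <- synth_observable_series("plateau", offsets = c(0, 0, 1),
                                   seed = 2)
  r_off <- equilibration_check(s_off)
  expect_true(r_off$condition_plateau)
  expect_false(r_off$condition_agreement)

  expect_error(equilibration_check(s_ok[s_ok$replica == 1, ]),
               "2 replicas")
  short <- s_ok[s_ok$time <= 21, ]
  expect_error(equilibration_check(short, window_fraction = 0.1),
               "5 points")
})
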