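test_that("dihedrals of constructed geometry are recovered exactly", {
  ## extended (zigzag) backbone: phi = psi = 180 at interior residues
  tpl <- toy_chain(8, phi = 180, psi = 180, chi1 = 60, chi2 = -75)
  ens <- trajectory_ensemble(tpl$coords, tpl$atoms)
  dih <- compute_dihedrals(ens)

  expect_true(is.na(dih$phi[dih$residue == 1]))       # no preceding C
  expect_true(is.na(dih$psi[dih$residue == 8]))       # no following N
  interior <- dih[dih$residue %in% 2:7, ]
  expect_equal(abs(interior$phi), rep(180, 6), tolerance = 1e-6)
  expect_equal(abs(interior$psi), rep(180, 6), tolerance = 1e-6)

  chi_ok <- dih[!is.na(dih$chi1), ]
  expect_equal(chi_ok$chi1, rep(60, nrow(chi_ok)), tolerance = 1e-6)
  chi2_ok <- dih[!is.na(dih$chi2), ]
  expect_equal(chi2_ok$chi2, rep(-75, nrow(chi2_ok)), tolerance = 1e-6)

  ## arbitrary dihedrals are rebuilt and recovered too
  tpl2 <- toy_chain(10, phi = c(-63, -120, -57, -70, -100, -45, -63, -80,
                                -110, -60),
                    psi = c(-42, 130, -40, -35, 120, -50, -45, 140, 110,
                            -40), chi1 = -170, chi2 = 55)
  dih2 <- compute_dihedrals(trajectory_ensemble(tpl2$coords, tpl2$atoms))
  got_phi <- dih2$phi[dih2$residue %in% 2:10]
  expect_equal(got_phi, tpl2$phi[2:10], tolerance = 1e-6)
  got_psi <- dih2$psi[dih2$residue %in% 1:9]
  expect_equal(got_psi, tpl2$psi[1:9], tolerance = 1e-6)

  ## rigid motion leaves all dihedrals unchanged
  r0 <- random_rotation(9)
  co <- tpl2$coords %*% t(r0) + 7
  dih3 <- compute_dihedrals(trajectory_ensemble(co, tpl2$atoms))
  expect_equal(dih3$phi, dih2$phi, tolerance = 1e-8)
  expect_equal(dih3$chi1, dih2$chi1, tolerance = 1e-8)

  ## collinear defining atoms give NA, not zero
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_true(is.na(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])))
})

test_that("sin/cos featurization has the documented width and ordering", {
  ## synthetic records covering the study's residue counts:
  ## 93 Ramachandran + 60 Janin pairs -> 612 features
  set.seed(3)
  nr <- 95
  rec <- tidyr::expand_grid(chain = 1:2, frame = 1:2,
                            residue = seq_len(nr))
  rec$residue_name <- "GLN"
  rec$phi <- runif(nrow(rec), -180, 180)
  rec$psi <- runif(nrow(rec), -180, 180)
  rec$chi1 <- runif(nrow(rec), -180, 180)
  rec$chi2 <- runif(nrow(rec), -180, 180)
  rama <- 2:94                       # 93 residues with phi and psi
  janin <- seq_len(60)               # 60 residues with chi1 and chi2
  fm <- featurize_sincos(rec, rama, janin)
  expect_equal(ncol(fm$x), 612)
  expect_equal(ncol(fm$x), (93 + 60) * 2 * 2)
  expect_equal(nrow(fm$x), 4)
  ## all features within [-1, 1]
  expect_true(all(fm$x >= -1 & fm$x <= 1))
  ## ordering: residue-major, phi before psi, sin before cos
  expect_equal(fm$features[1:4],
               c("phi_2_sin", "phi_2_cos", "psi_2_sin", "psi_2_cos"))

  ## phi = 90 -> (sin, cos) = (1, 0)
  rec90 <- rec[rec$chain == 1 & rec$frame == 1, ]
  rec90$phi <- 90
  fm90 <- featurize_sincos(rec90, rama, janin)
  expect_equal(unname(fm90$x[1, "phi_2_sin"]), 1)
  expect_equal(unname(fm90$x[1, "phi_2_cos"]), 0, tolerance = 1e-15)

  ## round trip: atan2 recovers the angles to 1e-9 degrees
  ang <- atan2(fm$x[, "chi1_7_sin"], fm$x[, "chi1_7_cos"]) * 180 / pi
  expect_equal(sort(ang), sort(rec$chi1[rec$residue == 7]),
               tolerance = 1e-9)

  ## an undefined angle inside the mask is an invalid-mask error
  rec_na <- rec
  rec_na$phi[rec_na$residue == 10] <- NA
  expect_error(featurize_sincos(rec_na, rama, janin), "invalid mask")
})

test_that("C-alpha distance features count n(n-1)/2 pairs", {
  tpl <- toy_chain(10, seed = 1)
  ens <- trajectory_ensemble(tpl$coords, tpl$atoms)
  fm3 <- featurize_ca_distances(ens, exclude_residues = 4:10)
  expect_equal(ncol(fm3$x), 3)

  ## the study's 88 included residues (95 minus the 7-residue tail)
  expect_equal(88 * 87 / 2, 3828)
  fm_all <- featurize_ca_distances(ens)
  expect_equal(ncol(fm_all$x), 10 * 9 / 2)
  expect_true(all(fm_all$x > 0))

  expect_error(featurize_ca_distances(ens, exclude_residues = 2:10),
               "at least 2")

  ## equilateral triangle: all three features equal
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  at <- tibble::tibble(atom_name = "CA", residue_index = 1:3,
                       residue_name = "GLY")
  fme <- featurize_ca_distances(trajectory_ensemble(tri, at))
  expect_equal(as.numeric(fme$x), rep(1, 3), tolerance = 1e-12)
})

test_that("PCA explains a line by one component and respects symmetry", {
  ## points on a line: PC1 explains everything
  set.seed(2)
  t_ <- rnorm(40)
  x <- cbind(2 * t_, -t_ + 3)
  fm <- xtalmd:::new_feature_matrix(x, c("f1", "f2"),
                                    tibble::tibble(chain = 1:40, frame = 1))
  p <- pca_fit(fm, 2)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)
  ## explained-variance fractions non-increasing, summing to 1 at full rank
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-12)

  ## the mean sample projects to the origin
  mean_proj <- predict(p, rbind(colMeans(x)))
  expect_equal(as.numeric(unlist(mean_proj)), c(0, 0), tolerance = 1e-12)

  ## duplicated feature column: equal absolute loadings on the duplicates;
  ## oracle = brute-force eigendecomposition of the covariance
  y <- cbind(t_, t_, rnorm(40, 0, 0.1))
  fmd <- xtalmd:::new_feature_matrix(y, c("a", "a_dup", "b"),
                                     tibble::tibble(chain = 1:40, frame = 1))
  pd <- pca_fit(fmd, 1)
  expect_equal(abs(pd$loadings[1, 1]), abs(pd$loadings[2, 1]),
               tolerance = 1e-9)
  ev <- eigen(stats::cov(y))$vectors[, 1]
  expect_equal(abs(pd$loadings[, 1]), abs(ev), tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(pca_fit(xtalmd:::new_feature_matrix(
    matrix(1, 5, 2), c("c1", "c2"),
    tibble::tibble(chain = 1:5, frame = 1))), "zero-variance")
})

test_that("LDA importance finds the separating feature and dies under permutation", {
  set.seed(5)
  n <- 80; p <- 10
  x <- matrix(rnorm(n * p), n)
  g <- rep(c("a", "b"), each = n / 2)
  x[g == "b", 7] <- x[g == "b", 7] + 6     # separation >> noise at feature 7
  fm <- xtalmd:::new_feature_matrix(
    x, paste0("f", 1:p),
    tibble::tibble(chain = seq_len(n), frame = 1, group = g))
  l <- lda_importance(fm)
  expect_equal(l$importance$feature[1], "f7")
  expect_gt(l$importance$importance[1], 3 * l$importance$importance[2])

  ## identical group distributions: no feature stands out like f7 did
  x0 <- matrix(rnorm(n * p), n)
  fm0 <- xtalmd:::new_feature_matrix(
    x0, paste0("f", 1:p),
    tibble::tibble(chain = seq_len(n), frame = 1, group = g))
  l0 <- lda_importance(fm0)
  expect_lt(max(l0$importance$importance) /
              stats::median(l0$importance$importance), 20)

  ## label permutation destroys the separation signal
  set.seed(6)
  fm_perm <- fm
  fm_perm$samples$group <- sample(g)
  lp <- lda_importance(fm_perm)
  expect_false(lp$importance$feature[1] == "f7" &&
                 lp$importance$importance[1] >
                   3 * lp$importance$importance[2])

  expect_error(lda_importance(xtalmd:::new_feature_matrix(
    x, paste0("f", 1:p), tibble::tibble(chain = seq_len(n), frame = 1))),
    "group")
})

test_that("rotamer populations and total variation distance behave", {
  ## all frames at chi1 = chi2 = 60: (g+, g+) population 1
  rec <- tibble::tibble(chain = 1, frame = 1:50, residue = 1,
                        residue_name = "GLN", chi1 = 60, chi2 = 60)
  rt <- rotamer_populations(rec, "GLN")
  expect_equal(sum(rt$population), 1, tolerance = 1e-9)
  expect_equal(rt$population[rt$chi1_state == "g+" &
                               rt$chi2_state == "g+"], 1)

  ## uniform angles: every cell near 1/9
  set.seed(10)
  recu <- tibble::tibble(chain = 1, frame = seq_len(20000), residue = 1,
                         residue_name = "GLU",
                         chi1 = runif(20000, -180, 180),
                         chi2 = runif(20000, -180, 180))
  rtu <- rotamer_populations(recu, "GLU")
  expect_equal(nrow(rtu), 9)
  expect_true(all(abs(rtu$population - 1 / 9) < 0.01))

  ## TVD: zero on self, symmetric, in [0, 1]
  expect_equal(rotamer_tvd(rt, rt)$tvd, 0)
  rt2 <- rt
  rt2$population <- rep(1 / 9, 9)
  d12 <- rotamer_tvd(rt, rt2)$tvd
  d21 <- rotamer_tvd(rt2, rt)$tvd
  expect_equal(d12, d21)
  expect_gte(d12, 0); expect_lte(d12, 1)
  expect_equal(d12, 8 / 9, tolerance = 1e-9)

  expect_error(rotamer_populations(rec, "TRP"), "empty selection")
})
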