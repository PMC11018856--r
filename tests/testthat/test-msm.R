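test_that("microstate clustering is deterministic and separates point clouds", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  cl <- cluster_microstates(x, 2, seed = 1)
  dt <- cl$dtrajs[[1]]
  expect_equal(dt[1], dt[2])
  expect_equal(dt[3], dt[4])
  expect_false(dt[1] == dt[3])

  ## k = 1: everything in one state
  expect_equal(unique(cluster_microstates(x, 1)$dtrajs[[1]]), 1L)

  ## determinism: same seed, same assignment
  set.seed(99); y <- matrix(rnorm(600), ncol = 2)
  a <- cluster_microstates(y, 5, seed = 7)
  b <- cluster_microstates(y, 5, seed = 7)
  expect_identical(a$dtrajs, b$dtrajs)
  expect_identical(a$centers, b$centers)

  expect_error(cluster_microstates(matrix(c(1, 1, 1), ncol = 1), 2),
               "distinct")
})

test_that("transition counts respect lags and trajectory boundaries", {
  ## hand enumeration
  counts <- transition_counts(c(1, 1, 2, 2, 1), 1)
  expect_equal(counts, rbind(c(1, 1), c(1, 1)))

  ## constant trajectory of length L at lag 1: L - 1 self-counts
  expect_equal(transition_counts(rep(1L, 20), 1)[1, 1], 19)

  ## separate trajectories differ from their concatenation only at the seam
  t1 <- c(1, 2, 1, 1); t2 <- c(2, 2, 1, 2)
  sep <- transition_counts(list(t1, t2), 1)
  joined <- transition_counts(c(t1, t2), 1)
  seam <- matrix(0, 2, 2); seam[t1[4], t2[1]] <- 1
  expect_equal(joined, sep + seam)

  ## total count bookkeeping at higher lag
  lag <- 3
  expect_equal(sum(transition_counts(list(t1, t2), lag)),
               sum(pmax(lengths(list(t1, t2)) - lag, 0)))

  expect_error(transition_counts(t1, 0), "lag")
  expect_error(transition_counts(t1, 4), "longest")
})

test_that("transition-matrix estimation matches 2-state closed forms", {
  ## doubly stochastic counts
  m1 <- estimate_transition_matrix(rbind(c(2, 2), c(1, 1)))
  expect_equal(m1$transition_matrix, rbind(c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(m1$stationary, c(0.5, 0.5))

  ## T = [[0.9, 0.1], [0.2, 0.8]]: lambda2 = 0.7, pi = (2/3, 1/3)
  m2 <- estimate_transition_matrix(rbind(c(90, 10), c(20, 80)))
  expect_equal(m2$eigenvalues, c(1, 0.7), tolerance = 1e-12)
  expect_equal(m2$stationary, c(2 / 3, 1 / 3), tolerance = 1e-12)
  ## pi T = pi
  expect_equal(as.numeric(m2$stationary %*% m2$transition_matrix),
               m2$stationary, tolerance = 1e-10)
  ## rows sum to one
  expect_equal(rowSums(m2$transition_matrix), c(1, 1), tolerance = 1e-12)

  ## identity counts: no finite implied timescale, warning raised
  expect_warning(
    mi <- estimate_transition_matrix(diag(c(5, 5))),
    "infinite")
  expect_true(is.infinite(mi$timescales$timescale_ns[1]))

  ## two closed sets are rejected with the components named
  blocked <- rbind(c(5, 0, 0, 0), c(0, 5, 0, 0),
                   c(0, 0, 3, 2), c(0, 0, 2, 3))
  blocked[1, 2] <- 5; blocked[2, 1] <- 5
  expect_error(estimate_transition_matrix(blocked), "closed communicating")

  ## reversible estimate satisfies detailed balance to 1e-10
  set.seed(3)
  c_rand <- matrix(rpois(9, 20), 3)
  mr <- estimate_transition_matrix(c_rand, reversible = TRUE)
  db <- outer(mr$stationary, rep(1, 3)) * mr$transition_matrix
  expect_equal(db, t(db), tolerance = 1e-10)
})

test_that("estimators are invariant under state relabeling", {
  set.seed(4)
  dt <- sample(1:3, 3000, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  perm <- c(3, 1, 2)
  m_orig <- estimate_transition_matrix(transition_counts(dt, 1))
  m_perm <- estimate_transition_matrix(transition_counts(perm[dt], 1))
  expect_equal(sort(m_orig$eigenvalues), sort(m_perm$eigenvalues),
               tolerance = 1e-10)
  expect_equal(m_orig$stationary, m_perm$stationary[perm],
               tolerance = 1e-10)
})

test_that("implied timescales are flat for a Markovian chain and match theory", {
  ## p01 = p10 = 0.1: t2 = -1/ln(0.8) ~= 4.48 frames
  ts <- synth_two_state_distance(0.1, 0.1, 5, 12, 0.5, 2e5, seed = 5)
  dtraj <- as.integer(ts$distance > 8.5) + 1L
  scan <- implied_timescale_scan(dtraj, lags = c(1, 2, 4, 8),
                                 n_timescales = 1)
  t_true <- -1 / log(0.8)
  for (l in unique(scan$lag_frames)) {
    expect_rel_equal(scan$timescale_ns[scan$lag_frames == l], t_true, 0.1)
  }
  ## flatness diagnostic present after the first lag
  expect_true(all(is.finite(scan$rel_change[scan$lag_frames > 1])))
  expect_error(implied_timescale_scan(dtraj, lags = 4), "2 lags")
})

test_that("spectral lumping recovers metastable blocks and conserves probability", {
  t4 <- rbind(c(0.49, 0.49, 0.01, 0.01),
              c(0.49, 0.49, 0.01, 0.01),
              c(0.01, 0.01, 0.49, 0.49),
              c(0.01, 0.01, 0.49, 0.49))
  m4 <- estimate_transition_matrix(round(t4 * 1000))
  cg <- pcca_coarse_grain(m4, 2)
  expect_equal(cg$assignment[1], cg$assignment[2])
  expect_equal(cg$assignment[3], cg$assignment[4])
  expect_false(cg$assignment[1] == cg$assignment[3])
  ## populations are block sums of pi and conserve probability
  expect_equal(sum(cg$macro_populations), 1, tolerance = 1e-12)
  expect_equal(cg$macro_populations[cg$assignment[1]],
               sum(m4$stationary[1:2]), tolerance = 1e-10)

  ## identity lumping at n_macro = n_micro (chain with full positive
  ## spectrum; the block chain above has two zero eigenvalues)
  diag_heavy <- rbind(c(80, 10, 5, 5), c(10, 70, 10, 10),
                      c(5, 10, 75, 10), c(5, 10, 10, 75))
  m_full <- estimate_transition_matrix(diag_heavy)
  cg_id <- pcca_coarse_grain(m_full, 4)
  expect_equal(sort(unique(cg_id$assignment)), 1:4)
  expect_equal(as.integer(table(cg_id$assignment)), rep(1L, 4))

  ## block-metastable chain: slowest timescale survives lumping within 10%
  set.seed(12)
  n_steps <- 2e5
  dt <- integer(n_steps); dt[1] <- 1L
  u <- runif(n_steps)
  for (i in 2:n_steps) {
    p <- t4[dt[i - 1], ]
    dt[i] <- findInterval(u[i], cumsum(p)) + 1L
  }
  m_sim <- estimate_transition_matrix(transition_counts(dt, 1),
                                      lag_frames = 1)
  cg_sim <- pcca_coarse_grain(m_sim, 2, dtrajs = dt)
  lam2_macro <- sort(Re(eigen(cg_sim$macro_transition_matrix,
                              only.values = TRUE)$values),
                     decreasing = TRUE)[2]
  t2_macro <- -1 / log(lam2_macro)
  t2_micro <- m_sim$timescales$timescale_ns[1]
  expect_rel_equal(t2_macro, t2_micro, 0.1)

  expect_error(pcca_coarse_grain(m4, 10), "n_macro")
})

test_that("cross-validated eigenvalue scores separate metastable from iid data", {
  ## metastable two-state trajectories: score -> 2
  meta <- lapply(1:6, function(i) {
    s <- synth_two_state_distance(0.02, 0.02, 0, 10, 0.5, 3000,
                                  seed = 20 + i)
    matrix(s$distance, ncol = 1)
  })
  g_meta <- gmrq_cv_score(meta, k = 2, lag = 1, n_folds = 3, seed = 2)
  expect_gt(g_meta$score, 1.8)
  expect_lte(g_meta$score, 2 + 1e-9)

  ## iid noise: only the trivial eigenvalue survives
  set.seed(30)
  iid <- lapply(1:6, function(i) matrix(rnorm(3000), ncol = 1))
  g_iid <- gmrq_cv_score(iid, k = 2, lag = 1, n_folds = 3, seed = 2)
  expect_lt(g_iid$score, 1.2)

  expect_error(gmrq_cv_score(meta, k = 2, lag = 1, n_folds = 1), "n_folds")
})
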