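## shared fixtures: the study's unit cell and small deterministic chains

study_cell <- function() unit_cell(65.30, 39.45, 39.01, beta = 117.54)

## static ensemble: the same coordinates replicated over frames/chains
static_ensemble <- function(tpl, n_frames = 2, n_chains = 1) {
  na <- nrow(tpl$coords)
  co <- array(rep(tpl$coords, n_frames * n_chains),
              c(na, 3, n_frames, n_chains))
  trajectory_ensemble(co, tpl$atoms)
}

## random proper rotation matrix
random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
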