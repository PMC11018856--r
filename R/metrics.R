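#' Deviation of an ensemble from a reference structure
#'
#' Each chain-frame is superposed onto the reference on the chosen atom
#' selection before measuring. Two modes mirror the standard accuracy
#' plots for crystal simulations:
#' * `"rmsd_time"` -- per-frame RMSD per chain, summarised as mean and
#'   between-chain standard deviation per frame (the replica envelope),
#'   with the trailing-window mean `<RMSD>` attached as an attribute;
#' * `"msd_residue"` -- per-residue mean squared deviation of the C-alpha
#'   position, averaged over chains and frames.
#'
#' @param ens a [trajectory_ensemble()].
#' @param ref `n_atoms x 3` reference coordinates (same topology).
#' @param mode `"rmsd_time"` or `"msd_residue"`.
#' @param selection `"heavy"` or `"calpha"`: atoms used both for the fit
#'   and the measurement (MSD is always reported per C-alpha).
#' @param trail_fraction trailing fraction of frames entering `<RMSD>`
#'   (default 0.2).
#' @param per_chain return the full per-chain RMSD table instead of the
#'   per-frame summary.
#' @return A tibble; for `"rmsd_time"` columns `frame, time_ns, rmsd_mean,
#'   rmsd_sd` (attribute `trail_mean`), for `"msd_residue"` columns
#'   `residue, msd`.
#' @export
deviation_metrics <- function(ens, ref, mode = c("rmsd_time", "msd_residue"),
                              selection = c("heavy", "calpha"),
                              trail_fraction = 0.2, per_chain = FALSE) {
  mode <- match.arg(mode)
  selection <- match.arg(selection)
  sel <- atom_selection(ens, selection)
  ca <- which(ens$atoms$is_ca)
  nf <- n_frames(ens); nc <- n_chains(ens)

  if (mode == "rmsd_time") {
    r <- matrix(NA_real_, nc, nf)
    for (ch in seq_len(nc)) {
      for (f in seq_len(nf)) {
        r[ch, f] <- kabsch_superpose(ens$coords[, , f, ch], ref, sel)$rmsd
      }
    }
    if (per_chain) {
      out <- tidyr::expand_grid(chain = seq_len(nc), frame = seq_len(nf))
      out$time_ns <- ens$times[out$frame]
      out$rmsd <- r[cbind(out$chain, out$frame)]
    } else {
      out <- tibble(frame = seq_len(nf), time_ns = ens$times,
                    rmsd_mean = colMeans(r),
                    rmsd_sd = apply(r, 2, sd))
    }
    trail <- max(1L, ceiling(trail_fraction * nf))
    attr(out, "trail_mean") <- mean(r[, (nf - trail + 1L):nf])
    attr(out, "trail_fraction") <- trail_fraction
    out
  } else {
    acc <- numeric(length(ca))
    for (ch in seq_len(nc)) {
      for (f in seq_len(nf)) {
        fit <- kabsch_superpose(ens$coords[, , f, ch], ref, sel)
        acc <- acc + rowSums((fit$coords[ca, , drop = FALSE] -
                                ref[ca, , drop = FALSE])^2)
      }
    }
    tibble(residue = ens$atoms$residue_index[ca], msd = acc / (nc * nf))
  }
}

#' Iterative ensemble-average structure
#'
#' Superposes every chain-frame onto the running mean, recomputes the mean,
#' and iterates until the mean coordinates move less than `tol` (max atom
#' shift, Angstrom).
#'
#' @inheritParams deviation_metrics
#' @param selection atoms used for the superposition.
#' @param tol convergence threshold in Angstrom (default 1e-6).
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   last shift in the message.
#' @param ref optional reference; when given, the RMSD between the
#'   converged mean and `ref` (heavy atoms, after superposition) is
#'   attached as attribute `rmsd_to_ref`.
#' @return A list: `coords` (mean structure), `iterations`, `converged`.
#' @export
mean_structure <- function(ens, selection = "heavy", tol = 1e-6,
                           max_iter = 100, ref = NULL) {
  if (n_frames(ens) * n_chains(ens) < 2) abort("need at least 2 structures")
  sel <- atom_selection(ens, selection)
  nf <- n_frames(ens); nc <- n_chains(ens)
  m <- ens$coords[, , 1, 1]
  shift <- Inf
  for (it in seq_len(max_iter)) {
    acc <- matrix(0, n_atoms(ens), 3)
    for (ch in seq_len(nc)) {
      for (f in seq_len(nf)) {
        acc <- acc + kabsch_superpose(ens$coords[, , f, ch], m, sel)$coords
      }
    }
    new_m <- acc / (nf * nc)
    shift <- max(abs(new_m - m))
    m <- new_m
    if (shift < tol) {
      out <- list(coords = m, iterations = it, converged = TRUE)
      if (!is.null(ref)) {
        hv <- which(ens$atoms$is_heavy)
        attr(out, "rmsd_to_ref") <- kabsch_superpose(m, ref, hv)$rmsd
      }
      return(out)
    }
  }
  abort(sprintf("mean structure did not converge in %d iterations (last shift %.3g A)",
                max_iter, shift))
}

#' Native contacts of a reference structure
#'
#' Contacts are heavy-atom pairs closer than `cutoff` between residues at
#' least `min_seq_sep` apart in sequence -- the standard hard-cutoff
#' definition behind the fraction of native contacts Q.
#'
#' @param ref `n_atoms x 3` reference coordinates.
#' @param atoms atom metadata tibble (see [trajectory_ensemble()]).
#' @param cutoff contact distance cutoff in Angstrom (default 4.5).
#' @param min_seq_sep minimum residue separation `|i - j|` (default 4).
#' @return A tibble `atom_i, atom_j, ref_dist` (indices into `ref`).
#' @export
native_contacts <- function(ref, atoms, cutoff = 4.5, min_seq_sep = 4) {
  atoms <- complete_atom_table(atoms)
  hv <- which(atoms$is_heavy)
  d <- as.matrix(dist(ref[hv, , drop = FALSE]))
  res <- atoms$residue_index[hv]
  sep <- abs(outer(res, res, "-"))
  ok <- d < cutoff & sep >= min_seq_sep & upper.tri(d)
  idx <- which(ok, arr.ind = TRUE)
  tibble(atom_i = hv[idx[, 1]], atom_j = hv[idx[, 2]],
         ref_dist = d[idx])
}

#' Fraction of preserved native contacts (Q)
#'
#' @param coords `n_atoms x 3` coordinates of one frame.
#' @param contacts contact table from [native_contacts()].
#' @param tolerance_factor a contact is preserved when its instantaneous
#'   distance is at most `tolerance_factor` times the reference distance
#'   (default 1.2).
#' @return Q in `[0, 1]`.
#' @export
native_contacts_q <- function(coords, contacts, tolerance_factor = 1.2) {
  if (is.null(contacts) || nrow(contacts) == 0) abort("empty contact set")
  di <- coords[contacts$atom_i, , drop = FALSE]
  dj <- coords[contacts$atom_j, , drop = FALSE]
  d <- sqrt(rowSums((di - dj)^2))
  mean(d <= tolerance_factor * contacts$ref_dist)
}

#' Lattice and chain B-factors
#'
#' Crystallographic temperature factors computed from simulated
#' fluctuations, `B = (8 pi^2 / 3) RMSF^2` per C-alpha, in two modes:
#' * `"lattice"` -- every whole supercell frame is superposed once onto
#'   the reference lattice; fluctuations then include rigid-body chain
#'   motion within the lattice;
#' * `"chain"` -- each chain is individually superposed onto its own mean
#'   structure; fluctuations are internal only.
#' The difference `B_lattice - B_chain` isolates the rigid-body
#' contribution (about `8 pi^2 sigma_rb^2` for per-axis rigid-body noise
#' `sigma_rb`).
#'
#' @param ens a [trajectory_ensemble()].
#' @param mode `"lattice"` or `"chain"`.
#' @param ref reference lattice coordinates for `mode = "lattice"`
#'   (`n_atoms x 3 x n_chains`); defaults to the first frame.
#' @param b_exp optional per-C-alpha experimental B values; when given,
#'   the Pearson correlation is attached as attribute `pearson_r`.
#' @param selection atoms used for the superposition fits.
#' @return A tibble `residue, rmsf2, b` with class `bfactor_profile` and
#'   attribute `mode`.
#' @export
bfactors <- function(ens, mode = c("lattice", "chain"), ref = NULL,
                     b_exp = NULL, selection = "heavy") {
  mode <- match.arg(mode)
  if (n_frames(ens) < 2) abort("B-factors need at least 2 frames")
  sel <- atom_selection(ens, selection)
  ca <- which(ens$atoms$is_ca)
  nf <- n_frames(ens); nc <- n_chains(ens)
  na <- n_atoms(ens)

  ## aligned[atom, xyz, frame, chain]
  aligned <- array(NA_real_, c(na, 3, nf, nc))
  if (mode == "lattice") {
    if (is.null(ref)) ref <- ens$coords[, , 1, , drop = TRUE]
    if (length(dim(ref)) == 2L) dim(ref) <- c(dim(ref), 1L)
    ref_flat <- matrix(aperm(ref, c(1, 3, 2)), ncol = 3)
    sel_flat <- as.vector(outer(sel, (seq_len(nc) - 1L) * na, "+"))
    for (f in seq_len(nf)) {
      fr <- matrix(aperm(array(ens$coords[, , f, ], c(na, 3, nc)),
                         c(1, 3, 2)), ncol = 3)
      fit <- kabsch_superpose(fr, ref_flat, sel_flat)
      aligned[, , f, ] <- aperm(array(fit$coords, c(na, nc, 3)), c(1, 3, 2))
    }
    ## per-atom-per-chain fluctuation about its own mean position
  } else {
    for (ch in seq_len(nc)) {
      sub <- trajectory_ensemble(ens$coords[, , , ch, drop = FALSE],
                                 ens$atoms, ens$times)
      m <- mean_structure(sub, selection = sel)$coords
      for (f in seq_len(nf)) {
        aligned[, , f, ch] <- kabsch_superpose(ens$coords[, , f, ch], m, sel)$coords
      }
    }
  }
  mean_pos <- apply(aligned, c(1, 2, 4), mean)        # atom x 3 x chain
  dev2 <- sweep(aligned, c(1, 2, 4), mean_pos)^2
  rmsf2_atom_chain <- apply(dev2, c(1, 4), sum) / nf  # atom x chain
  rmsf2 <- rowMeans(rmsf2_atom_chain)[ca]
  out <- tibble(residue = ens$atoms$residue_index[ca],
                rmsf2 = rmsf2, b = (8 * pi^2 / 3) * rmsf2)
  class(out) <- c("bfactor_profile", class(out))
  attr(out, "mode") <- mode
  if (!is.null(b_exp)) {
    if (length(b_exp) != length(ca)) abort("`b_exp` must have one value per C-alpha")
    attr(out, "pearson_r") <- cor(out$b, b_exp)
  }
  out
}

#' Internal-motion covariance and its distance decay
#'
#' After superposing each chain onto its own mean structure, the scalar
#' (dot-product) covariance `C_ij = <dr_i . dr_j>` of C-alpha displacements
#' is pooled over chains and frames, binned by inter-atomic distance, and
#' fitted with `A * exp(-d / l)`.
#'
#' Least-squares superposition removes the six rigid-body modes of each
#' chain, so the observable covariance is the rigid-mode-projected kernel
#' `P K P'`, not `K` itself. The default fit therefore evaluates the model
#' through that projection (profile least squares over `l`, with `A`
#' solved linearly); the naive direct fit of `A exp(-d/l)` to the bin means
#' is reported alongside for comparison.
#'
#' @param ens a [trajectory_ensemble()] (>= 2 frames; >= 100 chain-frames
#'   recommended).
#' @param bin_width distance bin width in Angstrom (default 2).
#' @param method `"projected"` (default) or `"plain"` for the primary fit.
#' @param selection atoms entering the covariance (default `"calpha"`).
#' @return An object of class `covariance_decay`: list with the covariance
#'   matrix `C`, `bins` tibble (`center, mean_cov, n_pairs`), fitted
#'   `amplitude` and `decay_length` (Angstrom), `method`, `degenerate`
#'   flag, the naive fit (`naive`), and the mean coordinates used.
#' @export
covariance_analysis <- function(ens, bin_width = 2,
                                method = c("projected", "plain"),
                                selection = "calpha") {
  method <- match.arg(method)
  sel <- atom_selection(ens, selection)
  nf <- n_frames(ens); nc <- n_chains(ens)
  if (nf * nc < 10) abort("too few chain-frames for covariance analysis")
  n <- length(sel)

  ## per-chain superposition to own mean, pooled deviations
  devs <- vector("list", nc)
  means <- vector("list", nc)
  for (ch in seq_len(nc)) {
    sub <- trajectory_ensemble(ens$coords[sel, , , ch, drop = FALSE],
                               ens$atoms[sel, ], ens$times)
    m <- mean_structure(sub, selection = seq_len(n))$coords
    a <- array(NA_real_, c(n, 3, nf))
    for (f in seq_len(nf)) {
      a[, , f] <- kabsch_superpose(sub$coords[, , f, 1], m)$coords
    }
    mpos <- apply(a, c(1, 2), mean)
    devs[[ch]] <- sweep(a, c(1, 2), mpos)
    means[[ch]] <- mpos
  }
  ## common frame for the mean coordinates: superpose chain means on chain 1
  mean_coords <- means[[1]]
  if (nc > 1) {
    acc <- means[[1]]
    for (ch in 2:nc) acc <- acc + kabsch_superpose(means[[ch]], means[[1]])$coords
    mean_coords <- acc / nc
  }

  cmat <- matrix(0, n, n)
  total <- 0L
  for (ch in seq_len(nc)) {
    d <- devs[[ch]]
    for (a_ in 1:3) cmat <- cmat + tcrossprod(d[, a_, ])
    total <- total + nf
  }
  cmat <- cmat / total

  dmat <- as.matrix(dist(mean_coords))
  ut <- upper.tri(dmat)
  bin_id <- floor(dmat[ut] / bin_width)
  bins <- tibble(
    center = (sort(unique(bin_id)) + 0.5) * bin_width,
    mean_cov = as.numeric(tapply(cmat[ut], bin_id, mean)),
    n_pairs = as.integer(table(bin_id))
  )
  if (all(bins$mean_cov <= 0)) {
    cnd <- rlang::error_cnd(class = "xtalmd_degenerate_covariance",
                            message = "non-positive covariances throughout; no decay to fit",
                            bins = bins)
    rlang::cnd_signal(cnd)
  }

  ## bins are weighted by pair count: a bin mean over n pairs has
  ## variance ~ 1/n, so weighted least squares is the natural estimator
  wts <- bins$n_pairs
  fit_plain <- tryCatch(suppressWarnings({
    keep <- bins$mean_cov > 0
    ft <- nls(y ~ A * exp(-x / l),
              data = list(x = bins$center[keep], y = bins$mean_cov[keep]),
              weights = wts[keep],
              start = list(A = max(bins$mean_cov), l = max(bin_width, 5)),
              control = nls.control(maxiter = 200, warnOnly = TRUE))
    list(amplitude = coef(ft)[["A"]], decay_length = coef(ft)[["l"]])
  }), error = function(e) list(amplitude = NA_real_, decay_length = NA_real_))

  if (method == "projected") {
    proj <- rigid_mode_projector(mean_coords)
    model_bins <- function(l) {
      cm <- projected_kernel(exp(-dmat / l), proj)
      as.numeric(tapply(cm[ut], bin_id, mean))
    }
    sse <- function(l) {
      mm <- model_bins(l)
      a <- sum(wts * mm * bins$mean_cov) / sum(wts * mm^2)
      sum(wts * (bins$mean_cov - a * mm)^2)
    }
    upper <- max(dmat) * 2
    opt <- optimize(sse, c(bin_width / 4, upper))
    l_hat <- opt$minimum
    mm <- model_bins(l_hat)
    a_hat <- sum(wts * mm * bins$mean_cov) / sum(wts * mm^2)
    fitted <- a_hat * mm
    primary <- list(amplitude = a_hat, decay_length = l_hat)
  } else {
    primary <- fit_plain
    fitted <- primary$amplitude * exp(-bins$center / primary$decay_length)
  }
  resid_sd <- sd(bins$mean_cov - fitted)
  degenerate <- !is.finite(primary$amplitude) ||
    primary$amplitude <= 2 * resid_sd

  structure(
    list(C = cmat, bins = dplyr::mutate(bins, fitted = fitted),
         amplitude = primary$amplitude, decay_length = primary$decay_length,
         method = method, degenerate = degenerate, naive = fit_plain,
         mean_coords = mean_coords,
         residues = ens$atoms$residue_index[sel]),
    class = "covariance_decay"
  )
}

#' @export
print.covariance_decay <- function(x, ...) {
  cat(sprintf("<covariance_decay> %d sites, fit (%s): A = %.3g A^2, l = %.3g A%s\n",
              nrow(x$C), x$method, x$amplitude, x$decay_length,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

## orthogonal projector onto the complement of the 6 rigid-body modes
## (3 translations + 3 infinitesimal rotations) at reference geometry X
rigid_mode_projector <- function(x) {
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  modes <- matrix(0, 3 * n, 6)
  for (a in 1:3) modes[seq(a, 3 * n, by = 3), a] <- 1
  rot <- list(
    cbind(0, -xc[, 3], xc[, 2]),   # e_x x r
    cbind(xc[, 3], 0, -xc[, 1]),   # e_y x r
    cbind(-xc[, 2], xc[, 1], 0)    # e_z x r
  )
  for (a in 1:3) modes[, 3 + a] <- as.vector(t(rot[[a]]))
  q <- qr.Q(qr(modes))
  diag(3 * n) - tcrossprod(q)
}

## scalar site covariance of P (K ox I3) P for an isotropic site kernel K
projected_kernel <- function(k, proj) {
  n <- nrow(k)
  k3 <- matrix(0, 3 * n, 3 * n)
  idx <- lapply(1:3, function(a) seq(a, 3 * n, by = 3))
  for (a in 1:3) k3[idx[[a]], idx[[a]]] <- k
  m <- proj %*% k3 %*% proj
  out <- matrix(0, n, n)
  for (a in 1:3) out <- out + m[idx[[a]], idx[[a]]]
  out
}

#' Equilibration diagnostics for replica observables
#'
#' Applies the two necessary conditions for equilibrium to per-replica time
#' series of a structural observable: (i) each replica's trailing window
#' must show no trend (least-squares slope within 2 block-bootstrap
#' standard errors of zero), and (ii) replicas started from different
#' initial conditions must become indistinguishable (all pairwise
#' differences of trailing-window means within 2 pooled standard errors).
#'
#' @param series tibble with columns `replica`, `time`, `value` (>= 2
#'   replicas, >= 20 points each).
#' @param window_fraction trailing fraction of each series used (default
#'   0.5; the window must contain >= 5 points).
#' @param n_boot block-bootstrap resamples for the standard errors.
#' @param seed RNG seed for the bootstrap.
#' @return An `equilibration_report`: list with `replicas` tibble
#'   (`replica, mean, se, slope, slope_se, plateau`), logical
#'   `condition_plateau`, `condition_agreement`, `equilibrated`, and the
#'   pairwise comparison table `pairs`.
#' @export
equilibration_check <- function(series, window_fraction = 0.5,
                                n_boot = 200, seed = 1) {
  reps <- unique(series$replica)
  if (length(reps) < 2) abort("need at least 2 replicas")
  counts <- table(series$replica)
  if (any(counts < 20)) abort("each replica needs at least 20 points")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  per <- lapply(reps, function(r) {
    sub <- series[series$replica == r, ]
    sub <- sub[order(sub$time), ]
    w <- ceiling(window_fraction * nrow(sub))
    if (w < 5) abort("trailing window shorter than 5 points")
    v <- tail(sub$value, w); t_ <- tail(sub$time, w)
    fit <- lm(v ~ t_)
    blk <- max(2L, floor(sqrt(w)))
    nblk <- ceiling(w / blk)
    boot <- replicate(n_boot, {
      starts <- sample.int(w - blk + 1L, nblk, replace = TRUE)
      idx <- as.vector(outer(0:(blk - 1L), starts, "+"))[1:w]
      vb <- v[idx]
      c(mean(vb), coef(lm(vb ~ t_))[2])
    })
    tibble(replica = r, mean = mean(v), se = sd(boot[1, ]),
           slope = coef(fit)[[2]], slope_se = sd(boot[2, ]),
           plateau = abs(coef(fit)[[2]]) <= 2 * sd(boot[2, ]))
  })
  per <- dplyr::bind_rows(per)

  prs <- utils::combn(seq_along(reps), 2)
  pairs <- tibble(
    replica_a = reps[prs[1, ]], replica_b = reps[prs[2, ]],
    diff = abs(per$mean[prs[1, ]] - per$mean[prs[2, ]]),
    pooled_se = sqrt(per$se[prs[1, ]]^2 + per$se[prs[2, ]]^2)
  )
  pairs$agree <- pairs$diff <= 2 * pairs$pooled_se

  structure(
    list(replicas = per, pairs = pairs,
         condition_plateau = all(per$plateau),
         condition_agreement = all(pairs$agree),
         equilibrated = all(per$plateau) && all(pairs$agree)),
    class = "equilibration_report"
  )
}

#' @export
print.equilibration_report <- function(x, ...) {
  cat(sprintf("<equilibration_report> plateau: %s  replica agreement: %s  => %s\n",
              x$condition_plateau, x$condition_agreement,
              if (x$equilibrated) "equilibrated" else "NOT equilibrated"))
  invisible(x)
}

## save/restore global RNG state so seeded internals do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
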