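## Internal-coordinate atom placement (bond length, bond angle, dihedral
## relative to three previously placed atoms) -- the standard NeRF step.
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  th <- angle_deg * pi / 180
  ph <- dihedral_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + cbind(bc, m, n) %*% d2
}

#' Toy polypeptide template with settable dihedrals
#'
#' Builds an idealized-geometry chain (N, CA, C, O backbone plus CB/CG/CD
#' side-chain stubs depending on residue type) from backbone and
#' side-chain dihedrals. With default arguments the conformation is a
#' seeded helix/strand mixture, giving a compact fold-like template;
#' explicit `phi`/`psi` (e.g. 180/180) give ideal extended geometry. The
#' template is the asymmetric unit of the synthetic crystal generator and
#' the fixture for dihedral-analysis tests: the dihedrals it is built
#' from are exactly recoverable from its coordinates.
#'
#' @param n_res number of residues (default 50).
#' @param phi,psi backbone dihedrals in degrees (scalar or length
#'   `n_res`); `NULL` draws a seeded helix/sheet mixture.
#' @param chi1,chi2 side-chain dihedrals (scalar or length `n_res`).
#' @param residue_names residue types; defaults to a fixed cycle
#'   including GLN and GLU.
#' @param seed seed for the default backbone draw.
#' @return A list with `coords` (`n_atoms x 3`), `atoms` metadata tibble,
#'   and the `phi, psi, chi1, chi2` used.
#' @export
toy_chain <- function(n_res = 50, phi = NULL, psi = NULL,
                      chi1 = -60, chi2 = 180,
                      residue_names = NULL, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(phi) || is.null(psi)) {
    helix <- runif(n_res) < 0.7
    phi_d <- ifelse(helix, -60, -120) + rnorm(n_res, 0, 10)
    psi_d <- ifelse(helix, -45, 120) + rnorm(n_res, 0, 10)
    if (is.null(phi)) phi <- phi_d
    if (is.null(psi)) psi <- psi_d
  }
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  chi1 <- rep_len(chi1, n_res); chi2 <- rep_len(chi2, n_res)
  if (is.null(residue_names)) {
    residue_names <- rep_len(c("GLN", "LEU", "GLU", "SER", "ALA",
                               "GLN", "GLY", "VAL", "GLU", "THR"), n_res)
  }
  residue_names <- rep_len(residue_names, n_res)
  has_cb <- residue_names != "GLY"
  has_cg <- !(residue_names %in% c("GLY", "ALA"))
  has_cd <- residue_names %in% c("GLN", "GLU", "LYS", "MET", "ARG", "PRO")

  coords <- list(); meta <- list()
  add <- function(name, r, xyz) {
    coords[[length(coords) + 1L]] <<- as.numeric(xyz)
    meta[[length(meta) + 1L]] <<- tibble(
      atom_name = name, residue_index = r, residue_name = residue_names[r])
  }
  n_prev <- ca_prev <- c_prev <- NULL
  for (r in seq_len(n_res)) {
    if (r == 1) {
      n_ <- c(0, 0, 0)
      ca <- c(1.458, 0, 0)
      c_ <- ca + 1.525 * c(-cospi(111.2 / 180), sinpi(111.2 / 180), 0)
    } else {
      n_ <- as.numeric(place_atom(n_prev, ca_prev, c_prev, 1.329, 116.2,
                                  psi[r - 1]))
      ca <- as.numeric(place_atom(ca_prev, c_prev, n_, 1.458, 121.7, 180))
      c_ <- as.numeric(place_atom(c_prev, n_, ca, 1.525, 111.2, phi[r]))
    }
    add("N", r, n_); add("CA", r, ca); add("C", r, c_)
    o_psi <- if (r < n_res) psi[r] else 180
    add("O", r, place_atom(n_, ca, c_, 1.231, 120.8, o_psi + 180))
    if (has_cb[r]) {
      cb <- as.numeric(place_atom(c_, n_, ca, 1.53, 110.5, 122.7))
      add("CB", r, cb)
      if (has_cg[r]) {
        cg <- as.numeric(place_atom(n_, ca, cb, 1.52, 114, chi1[r]))
        add("CG", r, cg)
        if (has_cd[r]) {
          add("CD", r, place_atom(ca, cb, cg, 1.52, 114, chi2[r]))
        }
      }
    }
    n_prev <- n_; ca_prev <- ca; c_prev <- c_
  }
  list(coords = do.call(rbind, coords),
       atoms = complete_atom_table(dplyr::bind_rows(meta)),
       phi = phi, psi = psi, chi1 = chi1, chi2 = chi2)
}

#' Synthetic crystal-trajectory specification
#'
#' Collects the parameters of the synthetic crystal generator, with
#' defaults emulating the study conditions of a PDZ-domain crystal: the
#' C121 cell a = 65.30, b = 39.45, c = 39.01 Angstrom, beta = 117.54
#' degrees, a 3x3x3 supercell (108 chains), per-axis rigid-body noise
#' `sigma_rb = 1` Angstrom (lattice disorder amplitude
#' `1.596 * sigma_rb ~ 1.6` Angstrom), per-axis internal noise
#' `sigma_int = 0.5` Angstrom with spatial correlation length
#' `ell = 11` Angstrom, and a two-state loop distance with switching
#' probabilities 0.02/0.08 per frame (stationary populations 0.8/0.2)
#' between means 5.4 and 12 Angstrom.
#'
#' @param template chain template, as from [toy_chain()] (>= 4 atoms).
#' @param cell a [unit_cell()].
#' @param n_cells supercell dimensions.
#' @param space_group `"C121"` or `"P1"`.
#' @param sigma_int,sigma_rb per-axis internal and rigid-body noise, in
#'   Angstrom.
#' @param ell correlation length of the internal-noise kernel
#'   `exp(-d / ell)` in Angstrom (`0` = independent atoms).
#' @param loop two-state loop parameters
#'   (`list(p01, p10, mu0, mu1, sigma_d, res_anchor, res_loop)`), or
#'   `NULL` to disable. `res_anchor`/`res_loop` default to residue 3 and
#'   the third-from-last residue.
#' @param water_sites number of tethered water sites (0 = none).
#' @param water_occupancy per-site presence probability, recycled.
#' @param n_frames,dt_ns number of frames and frame interval (ns).
#' @param replica replica identifier.
#' @param seed RNG seed; identical specs give identical trajectories.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(template = toy_chain(20),
                           cell = unit_cell(65.30, 39.45, 39.01,
                                            beta = 117.54),
                           n_cells = c(3, 3, 3), space_group = "C121",
                           sigma_int = 0.5, sigma_rb = 1.0, ell = 11,
                           loop = list(p01 = 0.02, p10 = 0.08,
                                       mu0 = 5.4, mu1 = 12, sigma_d = 1),
                           water_sites = 0, water_occupancy = 0.8,
                           n_frames = 100, dt_ns = 10,
                           replica = 1L, seed = 1) {
  if (nrow(template$coords) < 4) abort("template must have at least 4 atoms")
  if (any(c(sigma_int, sigma_rb) < 0) || ell < 0) {
    abort("noise parameters must be non-negative")
  }
  if (!is.null(loop)) {
    if (loop$p01 + loop$p10 >= 1) {
      abort("p01 + p10 must be < 1 (oscillatory regime excluded)")
    }
    if (loop$mu0 == loop$mu1) abort("loop state means must differ")
    nr <- max(template$atoms$residue_index)
    if (is.null(loop$res_anchor)) loop$res_anchor <- min(3L, nr)
    if (is.null(loop$res_loop)) loop$res_loop <- max(nr - 2L, 1L)
  }
  structure(
    list(template = template, cell = cell, n_cells = n_cells,
         space_group = space_group, sigma_int = sigma_int,
         sigma_rb = sigma_rb, ell = ell, loop = loop,
         water_sites = water_sites,
         water_occupancy = water_occupancy,
         n_frames = n_frames, dt_ns = dt_ns,
         replica = replica, seed = seed),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic crystal trajectory with known ground truth
#'
#' Chains are placed on the undistorted lattice by [build_supercell()];
#' every chain then receives, per frame, an independent rigid-body
#' translation `~ N(0, sigma_rb^2 I)` and internal per-atom displacements
#' drawn from a Gaussian with spatial covariance
#' `sigma_int^2 exp(-d_ij / ell)`. An optional hidden two-state Markov
#' process drives the distance between two marker residues (the loop
#' coordinate), and optional water molecules are tethered near protein
#' anchor atoms with a prescribed per-frame presence probability.
#'
#' @param spec a [synthetic_spec()].
#' @return A [trajectory_ensemble()] of noisy frames (the undistorted
#'   starting lattice is available as the `coords` element of
#'   [build_supercell()]). Attributes: `ground_truth` (true parameters, expected
#'   disorder amplitude, loop stationary populations and implied
#'   timescale, water occupancies, per-chain-frame loop states) and
#'   `waters` (per chain: list over frames of present water-oxygen
#'   coordinates) plus `water_sites_ref` (site positions in the template
#'   frame).
#' @export
synth_crystal_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  tpl <- spec$template
  na <- nrow(tpl$coords)
  sc <- build_supercell(tpl$coords, spec$cell, spec$n_cells,
                        spec$space_group, atoms = tpl$atoms)
  nc <- dim(sc$coords)[3]
  nf <- spec$n_frames

  ## internal-noise factor
  lmat <- NULL
  if (spec$sigma_int > 0) {
    if (spec$ell > 0) {
      k <- spec$sigma_int^2 * exp(-as.matrix(dist(tpl$coords)) / spec$ell)
      lmat <- chol(k + diag(1e-10, na))
    } else {
      lmat <- diag(spec$sigma_int, na)
    }
  }

  ## loop bookkeeping
  loop <- spec$loop
  loop_states <- NULL
  if (!is.null(loop)) {
    ca_a <- which(tpl$atoms$residue_index == loop$res_anchor &
                    tpl$atoms$atom_name == "CA")
    ca_l <- which(tpl$atoms$residue_index == loop$res_loop &
                    tpl$atoms$atom_name == "CA")
    loop_atoms <- which(tpl$atoms$residue_index == loop$res_loop)
    loop_states <- matrix(NA_integer_, nc, nf)
    pi1 <- loop$p01 / (loop$p01 + loop$p10)
  }

  ## water sites in the template frame, tethered to the 3 nearest heavy
  ## atoms: waters ride the rigid motion plus the mean internal
  ## displacement of their anchors
  nw <- spec$water_sites
  site_ref <- NULL; q <- NULL; site_anchor <- NULL; site_sc <- NULL
  if (nw > 0) {
    heavy <- which(tpl$atoms$is_heavy)
    site_ref <- matrix(NA_real_, nw, 3)
    placed <- 0L
    tries <- 0L
    while (placed < nw && tries < 1000L * nw) {
      tries <- tries + 1L
      host <- sample(heavy, 1)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      cand <- tpl$coords[host, ] + 2.8 * dir
      ## keep sites as distinct density peaks: >= 3.5 A apart
      if (placed > 0 &&
          min(sqrt(rowSums(sweep(site_ref[seq_len(placed), , drop = FALSE],
                                 2, cand)^2))) < 3.5) next
      placed <- placed + 1L
      site_ref[placed, ] <- cand
    }
    if (placed < nw) abort("could not place well-separated water sites")
    q <- rep_len(spec$water_occupancy, nw)
    ## tether each water to the same anchor set the tracker will use:
    ## all heavy atoms within 4 A (at least the 3 nearest)
    site_anchor <- lapply(seq_len(nw), function(i) {
      d <- sqrt(colSums((t(tpl$coords[heavy, , drop = FALSE]) -
                           site_ref[i, ])^2))
      sel <- heavy[d <= 4.0]
      if (length(sel) < 3) sel <- heavy[order(d)[1:3]]
      sel
    })
    site_sc <- build_supercell(site_ref, spec$cell, spec$n_cells,
                               spec$space_group)$coords
    if (length(dim(site_sc)) == 2L) dim(site_sc) <- c(dim(site_sc), 1L)
  }

  coords <- array(NA_real_, c(na, 3, nf, nc))
  waters <- if (nw > 0) {
    lapply(seq_len(nc), function(i) vector("list", nf))
  } else NULL

  for (ch in seq_len(nc)) {
    base <- sc$coords[, , ch]
    if (!is.null(loop)) {
      u <- base[ca_l, ] - base[ca_a, ]
      d_ref <- sqrt(sum(u^2))
      u <- u / d_ref
      s <- integer(nf)
      s[1] <- as.integer(runif(1) < pi1)
      if (nf > 1) {
        uu <- runif(nf - 1)
        for (t_ in 2:nf) {
          s[t_] <- if (s[t_ - 1] == 0L) as.integer(uu[t_ - 1] < loop$p01)
                   else as.integer(uu[t_ - 1] >= loop$p10)
        }
      }
      loop_states[ch, ] <- s
      d_t <- ifelse(s == 1L, loop$mu1, loop$mu0) + rnorm(nf, 0, loop$sigma_d)
    }
    int_disp <- if (is.null(lmat)) 0 else {
      z <- matrix(rnorm(na * 3 * nf), na)
      array(crossprod(lmat, z), c(na, 3, nf))
    }
    rb <- matrix(rnorm(3 * nf, 0, spec$sigma_rb), nf)
    for (f in seq_len(nf)) {
      x <- base
      if (!is.null(loop)) {
        x[loop_atoms, ] <- sweep(x[loop_atoms, , drop = FALSE], 2,
                                 (d_t[f] - d_ref) * u, "+")
      }
      if (!is.null(lmat)) x <- x + int_disp[, , f]
      x <- sweep(x, 2, rb[f, ], "+")
      coords[, , f, ch] <- x
      if (nw > 0) {
        present <- which(runif(nw) < q)
        w <- matrix(NA_real_, length(present), 3)
        for (k in seq_along(present)) {
          i <- present[k]
          anc <- site_anchor[[i]]
          local_disp <- if (is.null(lmat)) c(0, 0, 0) else
            colMeans(int_disp[anc, , f, drop = FALSE])
          w[k, ] <- site_sc[i, , ch] + rb[f, ] + local_disp +
            rnorm(3, 0, 0.1)
        }
        waters[[ch]][[f]] <- w
      }
    }
  }

  ens <- trajectory_ensemble(
    coords, tpl$atoms,
    times = spec$dt_ns * (seq_len(nf) - 1) + spec$dt_ns,
    replica = spec$replica, chains = sc$sites
  )
  truth <- list(
    sigma_int = spec$sigma_int, sigma_rb = spec$sigma_rb, ell = spec$ell,
    amplitude_expected = 2 * sqrt(2 / pi) * spec$sigma_rb,
    water_occupancy = q
  )
  if (!is.null(loop)) {
    truth$loop <- list(
      pi = c(loop$p10, loop$p01) / (loop$p01 + loop$p10),
      t_frames = -1 / log(1 - loop$p01 - loop$p10),
      states = loop_states
    )
  }
  attr(ens, "ground_truth") <- truth
  attr(ens, "sites") <- sc$sites
  attr(ens, "waters") <- waters
  attr(ens, "water_sites_ref") <- site_ref
  ens
}

#' Two-state Markov distance process
#'
#' Hidden two-state Markov chain (per-frame switching probabilities
#' `p01`, `p10`) emitting a Gaussian distance around the state mean --
#' the minimal generative model of a two-state loop coordinate. The
#' stationary populations are `(p10, p01) / (p01 + p10)` and the implied
#' relaxation timescale is `-1 / ln(1 - p01 - p10)` frames.
#'
#' @param p01,p10 switching probabilities per frame (`p01 + p10 < 1`).
#' @param mu0,mu1 state distance means in Angstrom (`mu0 != mu1`).
#' @param sigma_d emission width in Angstrom.
#' @param n_frames frames per chain.
#' @param n_chains independent chains (default 1).
#' @param seed RNG seed.
#' @return A tibble `chain, frame, distance, state` with attribute
#'   `ground_truth` (`pi`, `t_frames`, parameters).
#' @export
synth_two_state_distance <- function(p01, p10, mu0, mu1, sigma_d,
                                     n_frames, n_chains = 1, seed = 1) {
  if (p01 + p10 >= 1) abort("p01 + p10 must be < 1 (oscillatory regime excluded)")
  if (mu0 == mu1) abort("state means must differ")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pi1 <- p01 / (p01 + p10)
  out <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    s <- integer(n_frames)
    s[1] <- as.integer(runif(1) < pi1)
    if (n_frames > 1) {
      u <- runif(n_frames - 1)
      for (t_ in 2:n_frames) {
        s[t_] <- if (s[t_ - 1] == 0L) as.integer(u[t_ - 1] < p01)
                 else as.integer(u[t_ - 1] >= p10)
      }
    }
    d <- ifelse(s == 1L, mu1, mu0) + rnorm(n_frames, 0, sigma_d)
    out[[ch]] <- tibble(chain = ch, frame = seq_len(n_frames),
                        distance = d, state = s)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "ground_truth") <- list(
    pi = c(p10, p01) / (p01 + p10),
    t_frames = -1 / log(1 - p01 - p10),
    p01 = p01, p10 = p10, mu0 = mu0, mu1 = mu1, sigma_d = sigma_d
  )
  res
}

#' Synthetic dihedral ensembles with group-specific rotamer populations
#'
#' Emulates force-field-specific side-chain rotamer preferences: groups
#' share one backbone (phi/psi base values plus per-sample jitter) but
#' draw chi1/chi2 rotamer wells from group-specific 3x3 population
#' tables for the listed residue types. Angles are placed at the well
#' centre (g+ 60, t 180, g- -60 degrees) with uniform +/- `jitter`
#' degrees.
#'
#' @param groups named list; each element is a list with `residues`
#'   (tibble `residue, residue_name`, identical across groups) and
#'   `rotamers` (named list: residue type -> 3x3 population matrix, rows
#'   chi1 in order g+/t/g-, columns chi2).
#' @param n_samples conformations per group.
#' @param jitter uniform half-width around well centres in degrees
#'   (default 30, keeping draws inside their well).
#' @param backbone_sd per-sample backbone jitter sd in degrees.
#' @param seed RNG seed.
#' @return A tibble `group, replica, chain, frame, residue, residue_name,
#'   phi, psi, chi1, chi2` with attribute `ground_truth` (the tables).
#' @export
synth_dihedral_ensembles <- function(groups, n_samples = 100, jitter = 30,
                                     backbone_sd = 10, seed = 1) {
  res_ref <- groups[[1]]$residues
  for (g in groups) {
    if (!identical(g$residues$residue, res_ref$residue) ||
        !identical(g$residues$residue_name, res_ref$residue_name)) {
      abort("residue lists differ across groups")
    }
  }
  for (g in groups) {
    for (tab in g$rotamers) {
      if (any(tab < 0) || abs(sum(tab) - 1) > 1e-9) {
        abort("rotamer tables must be non-negative and sum to 1")
      }
    }
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nr <- nrow(res_ref)
  base_phi <- runif(nr, -150, -50)
  base_psi <- runif(nr, -60, 150)
  centers <- c("g+" = 60, "t" = 180, "g-" = -60)
  wrap <- function(a) ((a + 180) %% 360) - 180

  out <- purrr::map_dfr(names(groups), function(gn) {
    g <- groups[[gn]]
    purrr::map_dfr(seq_len(n_samples), function(s) {
      chi1 <- chi2 <- rep(NA_real_, nr)
      for (i in seq_len(nr)) {
        tab <- g$rotamers[[res_ref$residue_name[i]]]
        if (is.null(tab)) {
          cell <- c(3, 2)                  # shared (g-, t) well
        } else {
          pick <- sample.int(9, 1, prob = as.numeric(tab))
          cell <- c((pick - 1) %% 3 + 1, (pick - 1) %/% 3 + 1)
        }
        chi1[i] <- wrap(centers[cell[1]] + runif(1, -jitter, jitter))
        chi2[i] <- wrap(centers[cell[2]] + runif(1, -jitter, jitter))
      }
      tibble(group = gn, replica = (s - 1L) %% 3L + 1L, chain = s,
             frame = 1L,
             residue = res_ref$residue,
             residue_name = res_ref$residue_name,
             phi = wrap(base_phi + rnorm(nr, 0, backbone_sd)),
             psi = wrap(base_psi + rnorm(nr, 0, backbone_sd)),
             chi1 = chi1, chi2 = chi2)
    })
  })
  attr(out, "ground_truth") <- lapply(groups, `[[`, "rotamers")
  out
}

#' Synthetic replica observable series for equilibration checks
#'
#' `"plateau"`: AR(1) noise around a constant level (optionally offset
#' per replica); `"drift"`: a linear trend plus noise. The attached truth
#' records which equilibration condition should fail.
#'
#' @param kind `"plateau"` or `"drift"`.
#' @param n_replicas,n_points series dimensions.
#' @param level mean level; `offsets` (length `n_replicas`) shifts
#'   replicas individually.
#' @param noise_sd innovation sd; `ar` the AR(1) coefficient.
#' @param drift_slope slope per time unit for `"drift"`.
#' @param offsets per-replica level offsets.
#' @param seed RNG seed.
#' @return A tibble `replica, time, value` with attribute `ground_truth`.
#' @export
synth_observable_series <- function(kind = c("plateau", "drift"),
                                    n_replicas = 3, n_points = 100,
                                    level = 1, noise_sd = 0.1, ar = 0.5,
                                    drift_slope = 0.01, offsets = 0,
                                    seed = 1) {
  kind <- match.arg(kind)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  offsets <- rep_len(offsets, n_replicas)
  out <- purrr::map_dfr(seq_len(n_replicas), function(r) {
    eps <- as.numeric(stats::arima.sim(list(ar = ar), n_points,
                                       sd = noise_sd))
    v <- level + offsets[r] + eps
    if (kind == "drift") v <- v + drift_slope * seq_len(n_points)
    tibble(replica = r, time = seq_len(n_points), value = v)
  })
  attr(out, "ground_truth") <- list(
    kind = kind,
    should_fail_plateau = kind == "drift",
    should_fail_agreement = kind == "plateau" && any(offsets != offsets[1])
  )
  out
}
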