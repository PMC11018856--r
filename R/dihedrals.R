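#' Dihedral angle between four points
#'
#' Right-handed IUPAC sign convention; result in degrees in (-180, 180].
#' Collinear defining atoms give `NA` (flagged, never silently zero).
#'
#' @param p1,p2,p3,p4 `n x 3` matrices (or length-3 vectors) of the four
#'   defining atom positions.
#' @return Numeric vector of angles in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3); p4 <- rbind(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cross3(n1, n2) * b2) / b2n
  ang <- atan2(y, x) * 180 / pi
  bad <- rowSums(n1^2) < 1e-14 | rowSums(n2^2) < 1e-14
  ang[bad] <- NA_real_
  ang[ang <= -180] <- 180
  ang
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## standard dihedral atom quadruples per residue, as atom indices
dihedral_quadruples <- function(atoms) {
  res <- sort(unique(atoms$residue_index))
  find <- function(r, name) {
    i <- which(atoms$residue_index == r & atoms$atom_name == name)
    if (length(i)) i[1] else NA_integer_
  }
  purrr::map_dfr(res, function(r) {
    n_ <- find(r, "N"); ca <- find(r, "CA"); c_ <- find(r, "C")
    cp <- find(r - 1, "C"); nn <- find(r + 1, "N")
    cb <- find(r, "CB"); cg <- find(r, "CG"); cd <- find(r, "CD")
    tibble(
      residue = r,
      residue_name = atoms$residue_name[atoms$residue_index == r][1],
      phi_1 = cp, phi_2 = n_, phi_3 = ca, phi_4 = c_,
      psi_1 = n_, psi_2 = ca, psi_3 = c_, psi_4 = nn,
      chi1_1 = n_, chi1_2 = ca, chi1_3 = cb, chi1_4 = cg,
      chi2_1 = ca, chi2_2 = cb, chi2_3 = cg, chi2_4 = cd
    )
  })
}

#' Backbone and side-chain dihedrals of an ensemble
#'
#' Computes Ramachandran (phi, psi) and the first two side-chain dihedrals
#' (chi1: N-CA-CB-CG, chi2: CA-CB-CG-CD) for every residue, chain and
#' frame. Angles whose defining atoms are absent (chain termini, short
#' side chains) are `NA`.
#'
#' @param ens a [trajectory_ensemble()].
#' @return A tibble `chain, frame, time_ns, residue, residue_name, phi,
#'   psi, chi1, chi2` (degrees).
#' @export
compute_dihedrals <- function(ens) {
  quads <- dihedral_quadruples(ens$atoms)
  nf <- n_frames(ens); nc <- n_chains(ens)
  angs <- c("phi", "psi", "chi1", "chi2")
  out <- vector("list", nc * nf)
  k <- 0L
  for (ch in seq_len(nc)) {
    for (f in seq_len(nf)) {
      xyz <- ens$coords[, , f, ch]
      rec <- tibble(chain = ch, frame = f, time_ns = ens$times[f],
                    residue = quads$residue,
                    residue_name = quads$residue_name)
      for (a in angs) {
        idx <- as.matrix(quads[paste0(a, "_", 1:4)])
        ok <- stats::complete.cases(idx)
        v <- rep(NA_real_, nrow(quads))
        if (any(ok)) {
          v[ok] <- dihedral_angle(xyz[idx[ok, 1], , drop = FALSE],
                                  xyz[idx[ok, 2], , drop = FALSE],
                                  xyz[idx[ok, 3], , drop = FALSE],
                                  xyz[idx[ok, 4], , drop = FALSE])
        }
        rec[[a]] <- v
      }
      k <- k + 1L
      out[[k]] <- rec
    }
  }
  dplyr::bind_rows(out)
}

#' Sin/cos dihedral feature matrix
#'
#' Builds the per-conformation feature vector from fixed Ramachandran and
#' Janin residue sets: each angle contributes `(sin, cos)`, so the width is
#' `(nR + nJ) * 2 * 2` (612 for the 93 + 60 sets of a 95-residue PDZ
#' domain). Feature order is deterministic: Ramachandran residues first
#' (residue-major; phi then psi; sin before cos), then Janin residues
#' (chi1 then chi2).
#'
#' @param dihedrals tibble from [compute_dihedrals()] (or a compatible
#'   synthetic table; optional columns `group`, `replica` are carried into
#'   the sample metadata).
#' @param rama_residues,janin_residues residue indices of the Ramachandran
#'   and Janin sets; every masked residue must have the respective angles
#'   defined in every sample (an undefined angle is an error -- the mask
#'   is invalid).
#' @return A `feature_matrix`: list with the numeric matrix `x`
#'   (samples x features), `features` labels, and `samples` metadata
#'   (`chain`, `frame`, plus `group`/`replica` when present).
#' @export
featurize_sincos <- function(dihedrals, rama_residues, janin_residues) {
  key_cols <- intersect(c("group", "replica", "chain", "frame"),
                        names(dihedrals))
  samples <- dplyr::distinct(dihedrals[key_cols])
  ns <- nrow(samples)
  sample_id <- dplyr::left_join(
    dihedrals[key_cols],
    dplyr::mutate(samples, .sid = dplyr::row_number()),
    by = key_cols
  )$.sid

  blocks <- list()
  labels <- character(0)
  grab <- function(residues, angle) {
    m <- matrix(NA_real_, ns, length(residues))
    for (j in seq_along(residues)) {
      rows <- dihedrals$residue == residues[j]
      v <- dihedrals[[angle]][rows]
      if (anyNA(v)) {
        abort(sprintf("residue %d has undefined %s: invalid mask",
                      residues[j], angle))
      }
      m[sample_id[rows], j] <- v
    }
    if (anyNA(m)) abort("mask residues missing from some samples")
    m
  }
  for (a in c("phi", "psi")) {
    deg <- grab(rama_residues, a)
    blocks[[paste0(a, "_sin")]] <- sinpi(deg / 180)
    blocks[[paste0(a, "_cos")]] <- cospi(deg / 180)
  }
  for (a in c("chi1", "chi2")) {
    deg <- grab(janin_residues, a)
    blocks[[paste0(a, "_sin")]] <- sinpi(deg / 180)
    blocks[[paste0(a, "_cos")]] <- cospi(deg / 180)
  }
  ## residue-major ordering: for each residue, angle, then sin before cos
  x <- matrix(NA_real_, ns,
              4 * length(rama_residues) + 4 * length(janin_residues))
  col <- 0L
  for (j in seq_along(rama_residues)) {
    for (a in c("phi", "psi")) {
      for (fx in c("sin", "cos")) {
        col <- col + 1L
        x[, col] <- blocks[[paste0(a, "_", fx)]][, j]
        labels[col] <- sprintf("%s_%d_%s", a, rama_residues[j], fx)
      }
    }
  }
  for (j in seq_along(janin_residues)) {
    for (a in c("chi1", "chi2")) {
      for (fx in c("sin", "cos")) {
        col <- col + 1L
        x[, col] <- blocks[[paste0(a, "_", fx)]][, j]
        labels[col] <- sprintf("%s_%d_%s", a, janin_residues[j], fx)
      }
    }
  }
  colnames(x) <- labels
  new_feature_matrix(x, labels, samples)
}

new_feature_matrix <- function(x, features, samples) {
  structure(list(x = x, features = features, samples = as_tibble(samples)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' @export
as_tibble.feature_matrix <- function(x, ...) {
  dplyr::bind_cols(x$samples, as_tibble(x$x, .name_repair = "minimal"))
}

#' Pairwise C-alpha distance features
#'
#' All unordered C-alpha pair distances among the included residues:
#' `n (n - 1) / 2` features per conformation (3828 for the 88 residues
#' left after excluding a 7-residue C-terminal tail from a 95-residue
#' chain).
#'
#' @param ens a [trajectory_ensemble()].
#' @param exclude_residues residue indices left out (e.g. a disordered
#'   C-terminal tail).
#' @return A `feature_matrix` with labels `d_<i>_<j>`.
#' @export
featurize_ca_distances <- function(ens, exclude_residues = NULL) {
  ca <- which(ens$atoms$is_ca &
                !(ens$atoms$residue_index %in% exclude_residues))
  if (length(ca) < 2) abort("need at least 2 included residues")
  res <- ens$atoms$residue_index[ca]
  nf <- n_frames(ens); nc <- n_chains(ens)
  pair <- which(upper.tri(diag(length(ca))), arr.ind = TRUE)
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE]
  labels <- sprintf("d_%d_%d", res[pair[, 1]], res[pair[, 2]])
  x <- matrix(NA_real_, nc * nf, nrow(pair))
  samples <- tidyr::expand_grid(chain = seq_len(nc), frame = seq_len(nf))
  for (s in seq_len(nrow(samples))) {
    xyz <- ens$coords[ca, , samples$frame[s], samples$chain[s]]
    x[s, ] <- sqrt(rowSums((xyz[pair[, 1], ] - xyz[pair[, 2], ])^2))
  }
  colnames(x) <- labels
  new_feature_matrix(x, labels, samples)
}

#' Rotamer-state populations
#'
#' Classifies chi1/chi2 into the canonical wells g+ = `[0, 120)`,
#' t = `[120, 180] U (-180, -120)`, g- = `[-120, 0)` and tabulates the
#' 3x3 joint populations per residue type, with a standard error over
#' replicas when a `replica` column is present.
#'
#' @param dihedrals tibble with `residue_name`, `chi1`, `chi2` (degrees)
#'   and optionally `replica`.
#' @param residue_types residue types kept (e.g. `c("GLN", "GLU")`).
#' @return A `rotamer_table` tibble: `residue_name, chi1_state, chi2_state,
#'   population, se, n` (each type's 3x3 table sums to 1).
#' @export
rotamer_populations <- function(dihedrals, residue_types) {
  sub <- dihedrals[dihedrals$residue_name %in% residue_types &
                     !is.na(dihedrals$chi1) & !is.na(dihedrals$chi2), ]
  if (nrow(sub) == 0) abort("empty selection: no residues with chi1 and chi2")
  sub$chi1_state <- rotamer_state(sub$chi1)
  sub$chi2_state <- rotamer_state(sub$chi2)
  if (!"replica" %in% names(sub)) sub$replica <- 1L

  states <- c("g+", "t", "g-")
  grid <- tidyr::expand_grid(residue_name = unique(sub$residue_name),
                             chi1_state = states, chi2_state = states)
  per_rep <- sub %>%
    dplyr::count(.data$replica, .data$residue_name,
                 .data$chi1_state, .data$chi2_state) %>%
    dplyr::group_by(.data$replica, .data$residue_name) %>%
    dplyr::mutate(p = .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
  full <- tidyr::expand_grid(replica = unique(sub$replica), grid) %>%
    dplyr::left_join(per_rep,
                     by = c("replica", "residue_name", "chi1_state",
                            "chi2_state")) %>%
    dplyr::mutate(p = dplyr::coalesce(.data$p, 0))
  out <- full %>%
    dplyr::group_by(.data$residue_name, .data$chi1_state, .data$chi2_state) %>%
    dplyr::summarise(
      population = mean(.data$p),
      se = if (dplyr::n() > 1) sd(.data$p) / sqrt(dplyr::n()) else 0,
      .groups = "drop"
    )
  counts <- sub %>% dplyr::count(.data$residue_name, name = "n")
  out <- dplyr::left_join(out, counts, by = "residue_name")
  out <- out[order(out$residue_name,
                   match(out$chi1_state, states),
                   match(out$chi2_state, states)), ]
  class(out) <- c("rotamer_table", class(out))
  out
}

#' @rdname rotamer_populations
#' @param chi angle(s) in degrees.
#' @export
rotamer_state <- function(chi) {
  out <- rep(NA_character_, length(chi))
  out[chi >= 0 & chi < 120] <- "g+"
  out[(chi >= 120 & chi <= 180) | (chi > -180 & chi < -120)] <- "t"
  out[chi >= -120 & chi < 0] <- "g-"
  out[chi == -180] <- "t"
  out
}

#' Total variation distance between rotamer tables
#'
#' `TVD = 0.5 * sum |p - q|` over the 9 chi1 x chi2 cells, per residue
#' type shared by the two tables. Symmetric, in `[0, 1]`, zero iff equal.
#'
#' @param table1,table2 `rotamer_table`s from [rotamer_populations()] (or
#'   any tibble with `residue_name, chi1_state, chi2_state, population`,
#'   e.g. an external reference table).
#' @return A tibble `residue_name, tvd`.
#' @export
rotamer_tvd <- function(table1, table2) {
  j <- dplyr::inner_join(
    table1[c("residue_name", "chi1_state", "chi2_state", "population")],
    table2[c("residue_name", "chi1_state", "chi2_state", "population")],
    by = c("residue_name", "chi1_state", "chi2_state"),
    suffix = c("_1", "_2")
  )
  if (nrow(j) == 0) abort("tables share no residue types")
  j %>%
    dplyr::group_by(.data$residue_name) %>%
    dplyr::summarise(tvd = 0.5 * sum(abs(.data$population_1 -
                                           .data$population_2)),
                     .groups = "drop")
}
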