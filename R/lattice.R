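#' Unit-cell geometry
#'
#' Construct a crystallographic unit cell from lengths (Angstrom) and angles
#' (degrees). The Cartesian frame follows the monoclinic standard: **a**
#' along x, **b** along y, **c** in the x-z plane (the general triclinic
#' formula reduces to this when alpha = gamma = 90 degrees).
#'
#' @param a,b,c cell edge lengths in Angstrom (positive).
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell` with fields `a, b, c, alpha, beta,
#'   gamma` and the derived 3x3 `cell_matrix` whose columns are the cell
#'   vectors.
#' @examples
#' cell <- unit_cell(65.30, 39.45, 39.01, beta = 117.54)
#' unit_cell_matrix(cell)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (any(c(a, b, c) <= 0)) abort("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180)) {
    abort("cell angles must lie in (0, 180) degrees")
  }
  cell <- structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma),
    class = "unit_cell"
  )
  cell$cell_matrix <- unit_cell_matrix(cell)
  cell
}

#' @rdname unit_cell
#' @param cell a `unit_cell`.
#' @export
unit_cell_matrix <- function(cell) {
  if (!is.null(cell$cell_matrix)) return(cell$cell_matrix)
  ca <- cospi(cell$alpha / 180); cb <- cospi(cell$beta / 180)
  cg <- cospi(cell$gamma / 180); sg <- sinpi(cell$gamma / 180)
  av <- c(cell$a, 0, 0)
  bv <- cell$b * c(cg, sg, 0)
  cy <- (ca - cb * cg) / sg
  cz2 <- 1 - cb^2 - cy^2
  if (cz2 <= 1e-12) abort("degenerate unit cell (near-zero volume)")
  cv <- cell$c * c(cb, cy, sqrt(cz2))
  m <- cbind(av, bv, cv, deparse.level = 0)
  ## relative volume (fraction of the orthogonal a*b*c box)
  if (det(m) <= 1e-4 * cell$a * cell$b * cell$c) {
    abort("degenerate unit cell (near-zero volume)")
  }
  ## monoclinic convention: exact zeros where alpha = gamma = 90
  m[abs(m) < 1e-12] <- 0
  m
}

#' @rdname unit_cell
#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.2f b=%.2f c=%.2f A  alpha=%.2f beta=%.2f gamma=%.2f deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Fractional/Cartesian coordinate transforms
#'
#' @param x an `n x 3` matrix (or length-3 vector) of coordinates; rows are
#'   points.
#' @param cell a [unit_cell()].
#' @return An `n x 3` matrix in the other coordinate system.
#' @export
frac_to_cart <- function(x, cell) {
  x <- rbind(x)[, 1:3, drop = FALSE]
  x %*% t(unit_cell_matrix(cell))
}

#' @rdname frac_to_cart
#' @export
cart_to_frac <- function(x, cell) {
  x <- rbind(x)[, 1:3, drop = FALSE]
  x %*% t(solve(unit_cell_matrix(cell)))
}

#' Space-group symmetry operators
#'
#' Returns the symmetry operators of the supported space groups as
#' rotation matrices and fractional translations acting on fractional
#' coordinates (`f' = R f + t`). `"C121"` (C2, a C-centred monoclinic group
#' with a two-fold axis along b) carries four symmetry positions per cell:
#' (x,y,z); (-x,y,-z); (x+1/2,y+1/2,z); (-x+1/2,y+1/2,-z). `"P1"` (identity
#' only) is provided for testing.
#'
#' @param space_group `"C121"` or `"P1"`.
#' @return A list of operators, each a list with integer 3x3 `rotation` and
#'   numeric fractional `translation`.
#' @export
symmetry_operators <- function(space_group = "C121") {
  twofold_b <- diag(c(-1, 1, -1))
  ops <- switch(space_group,
    C121 = list(
      list(rotation = diag(3), translation = c(0, 0, 0)),
      list(rotation = twofold_b, translation = c(0, 0, 0)),
      list(rotation = diag(3), translation = c(0.5, 0.5, 0)),
      list(rotation = twofold_b, translation = c(0.5, 0.5, 0))
    ),
    P1 = list(list(rotation = diag(3), translation = c(0, 0, 0))),
    abort(sprintf("unknown space group '%s'; supported: C121, P1",
                  space_group))
  )
  lapply(ops, function(o) {
    o$rotation <- structure(o$rotation, dimnames = NULL)
    o
  })
}

apply_operator <- function(op, frac) {
  sweep(rbind(frac) %*% t(op$rotation), 2, op$translation, "+")
}

#' Build a crystal supercell from one asymmetric unit
#'
#' Replicates a single chain over the symmetry operators of the space group
#' and an `n1 x n2 x n3` block of unit cells. Chain order is deterministic:
#' cell-major (cells in lexicographic `(i, j, k)` order), operator-minor.
#'
#' @param asym_coords `n_atoms x 3` Cartesian coordinates (Angstrom) of the
#'   asymmetric unit, consistent with `cell`.
#' @param cell a [unit_cell()].
#' @param n_cells integer triple, e.g. `c(3, 3, 3)`.
#' @param space_group passed to [symmetry_operators()].
#' @param atoms optional atom metadata used for the mass-weighted
#'   centre-of-mass stored with each lattice site (equal masses otherwise).
#' @return A list with `coords` (`n_atoms x 3 x n_chains` array, the
#'   undistorted starting frame) and `sites`, a tibble of lattice sites
#'   (`chain`, `cell_i/j/k`, `operator`, ideal centre of mass `com_x/y/z`).
#'   For C121 and `n_cells = c(3, 3, 3)` there are 27 x 4 = 108 chains.
#' @export
build_supercell <- function(asym_coords, cell, n_cells = c(3, 3, 3),
                            space_group = "C121", atoms = NULL) {
  n_cells <- as.integer(n_cells)
  if (length(n_cells) != 3 || any(n_cells <= 0)) {
    abort("`n_cells` must be three positive integers")
  }
  ops <- symmetry_operators(space_group)
  frac <- cart_to_frac(asym_coords, cell)
  if (is.null(atoms)) {
    mass <- rep(1, nrow(asym_coords)); heavy <- NULL
  } else {
    atoms <- complete_atom_table(atoms)
    mass <- atoms$mass; heavy <- which(atoms$is_heavy)
  }
  cells <- expand.grid(k = seq_len(n_cells[3]) - 1L,
                       j = seq_len(n_cells[2]) - 1L,
                       i = seq_len(n_cells[1]) - 1L)[, c("i", "j", "k")]
  cells <- cells[order(cells$i, cells$j, cells$k), , drop = FALSE]
  n_ch <- nrow(cells) * length(ops)
  out <- array(NA_real_, c(nrow(asym_coords), 3, n_ch))
  sites <- vector("list", n_ch)
  ch <- 0L
  for (ci in seq_len(nrow(cells))) {
    shift <- as.numeric(cells[ci, ])
    for (oi in seq_along(ops)) {
      ch <- ch + 1L
      f <- sweep(apply_operator(ops[[oi]], frac), 2, shift, "+")
      xyz <- frac_to_cart(f, cell)
      out[, , ch] <- xyz
      com <- mass_com(xyz, mass, heavy)
      sites[[ch]] <- tibble(
        chain = ch, cell_i = cells[ci, 1], cell_j = cells[ci, 2],
        cell_k = cells[ci, 3], operator = oi,
        com_x = com[1], com_y = com[2], com_z = com[3]
      )
    }
  }
  list(coords = out, sites = dplyr::bind_rows(sites))
}

#' Inverse crystallographic transform of chain centres of mass
#'
#' Maps the centre of mass of every chain back into the asymmetric-unit
#' frame by inverting its lattice site's cell translation and symmetry
#' operator, then reports the displacement from the reference centre of
#' mass. In an undistorted lattice all displacements are zero; thermal
#' lattice vibrations scatter them around the origin.
#'
#' @param ens a [trajectory_ensemble()] whose chains were placed by
#'   [build_supercell()].
#' @param sites the `sites` tibble from [build_supercell()] (one row per
#'   chain, same order).
#' @param cell the reference [unit_cell()]. If the ensemble carries
#'   per-frame box matrices (`ens$box`), those are used to convert each
#'   frame's laboratory coordinates to fractional ones; the reference cell
#'   always maps the recovered fractional displacement back to Angstrom.
#' @param space_group passed to [symmetry_operators()].
#' @param ref_com optional reference centre of mass (length 3). Defaults
#'   to the back-transform of the ideal site centres of mass carried in
#'   `sites`, i.e. the asymmetric-unit centre of mass of the undistorted
#'   lattice -- exact, no estimation from the trajectory.
#' @return A tibble with one row per chain and frame: `chain`, `frame`,
#'   `time_ns`, displacement components `dx, dy, dz`, magnitude `dmag`, and
#'   the projection `ac_u`, `ac_v` onto the unit a- and c-axis directions
#'   (for disorder plots in the ac plane).
#' @export
inverse_lattice_transform <- function(ens, sites, cell,
                                      space_group = "C121", ref_com = NULL) {
  if (nrow(sites) != n_chains(ens)) {
    abort("chain/site count mismatch between `ens` and `sites`")
  }
  ops <- symmetry_operators(space_group)
  m_ref <- unit_cell_matrix(cell)
  heavy <- which(ens$atoms$is_heavy)
  mass <- ens$atoms$mass
  nf <- n_frames(ens); nc <- n_chains(ens)

  if (is.null(ref_com)) {
    ## ideal site COMs are forward transforms of one reference point:
    ## invert chain 1's transform to recover it exactly
    op1 <- ops[[sites$operator[1]]]
    shift1 <- as.numeric(sites[1, c("cell_i", "cell_j", "cell_k")])
    f1 <- as.numeric(solve(m_ref) %*%
                       c(sites$com_x[1], sites$com_y[1], sites$com_z[1]))
    ref_com <- as.numeric(
      m_ref %*% solve(op1$rotation) %*% (f1 - op1$translation - shift1))
  }

  back <- array(NA_real_, c(nc, nf, 3))
  for (f in seq_len(nf)) {
    m_f <- if (is.null(ens$box)) m_ref else ens$box[, , f]
    m_f_inv <- solve(m_f)
    for (ch in seq_len(nc)) {
      com <- mass_com(ens$coords[, , f, ch], mass, heavy)
      fl <- as.numeric(m_f_inv %*% com)
      op <- ops[[sites$operator[ch]]]
      shift <- as.numeric(sites[ch, c("cell_i", "cell_j", "cell_k")])
      f_asu <- as.numeric(solve(op$rotation) %*% (fl - op$translation - shift))
      back[ch, f, ] <- as.numeric(m_ref %*% f_asu)
    }
  }
  a_hat <- m_ref[, 1] / sqrt(sum(m_ref[, 1]^2))
  c_hat <- m_ref[, 3] / sqrt(sum(m_ref[, 3]^2))
  grid <- tidyr::expand_grid(chain = seq_len(nc), frame = seq_len(nf))
  d <- cbind(back[cbind(grid$chain, grid$frame, 1)] - ref_com[1],
             back[cbind(grid$chain, grid$frame, 2)] - ref_com[2],
             back[cbind(grid$chain, grid$frame, 3)] - ref_com[3])
  tibble(
    chain = grid$chain, frame = grid$frame,
    time_ns = ens$times[grid$frame], replica = ens$replica,
    dx = d[, 1], dy = d[, 2], dz = d[, 3],
    dmag = sqrt(rowSums(d^2)),
    ac_u = as.numeric(d %*% a_hat),
    ac_v = as.numeric(d %*% c_hat)
  )
}

#' Lattice disorder amplitude
#'
#' The mean magnitude of chain centre-of-mass displacement from its ideal
#' lattice site, over chains and frames -- the headline scalar of lattice
#' disorder. With independent per-axis Gaussian displacements of width
#' sigma the expected amplitude is `2*sqrt(2/pi)*sigma ~= 1.596*sigma`
#' (the mean of the 3-D Maxwell distribution).
#'
#' @param displacements tibble from [inverse_lattice_transform()] (needs a
#'   `dmag` column; a `replica` column, when present, yields per-replica
#'   statistics).
#' @return A one-row tibble: pooled `amplitude` (Angstrom), between-replica
#'   `sd` (NA for a single replica), `n_replicas`, `n_chain_frames`, plus a
#'   `per_replica` tibble attribute.
#' @export
disorder_amplitude <- function(displacements) {
  if (is.null(displacements) || nrow(displacements) == 0) {
    abort("empty displacement set")
  }
  if (!"replica" %in% names(displacements)) displacements$replica <- 1L
  per <- displacements %>%
    dplyr::group_by(replica = .data$replica) %>%
    dplyr::summarise(amplitude = mean(.data$dmag), n = dplyr::n(),
                     .groups = "drop")
  out <- tibble(
    amplitude = mean(displacements$dmag),
    sd = if (nrow(per) > 1) sd(per$amplitude) else NA_real_,
    n_replicas = nrow(per),
    n_chain_frames = nrow(displacements)
  )
  attr(out, "per_replica") <- per
  out
}
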