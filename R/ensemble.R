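#' Trajectory ensemble container
#'
#' The universal input of the package: per-chain, per-frame, per-atom
#' Cartesian coordinates together with atom metadata and frame times. All
#' chains share a single topology (the `atoms` table), which is the natural
#' situation for a crystal supercell built from one asymmetric unit.
#'
#' @param coords numeric array with dimensions
#'   `c(n_atoms, 3, n_frames, n_chains)`, in Angstrom. A `n_atoms x 3`
#'   matrix (single frame, single chain) or a `n_atoms x 3 x n_frames`
#'   array (single chain) is promoted.
#' @param atoms tibble of per-atom metadata with at least `atom_name`,
#'   `residue_index`, `residue_name`. Columns `element`, `mass`,
#'   `is_heavy` and `is_ca` are derived when absent.
#' @param times numeric vector of frame times in ns, strictly increasing.
#'   Defaults to `0, 1, ..., n_frames - 1`.
#' @param replica replica identifier (scalar), default `1L`.
#' @param chains optional tibble of per-chain metadata (one row per chain),
#'   e.g. the lattice-site bookkeeping attached by [build_supercell()].
#' @param box optional per-frame cell matrices: a single 3x3 matrix or a
#'   `3 x 3 x n_frames` array (columns are cell vectors in Angstrom).
#'
#' @return An object of class `trajectory_ensemble`.
#' @seealso [build_supercell()], [synth_crystal_trajectory()]
#' @export
trajectory_ensemble <- function(coords, atoms, times = NULL, replica = 1L,
                                chains = NULL, box = NULL) {
  if (is.matrix(coords)) dim(coords) <- c(dim(coords), 1L, 1L)
  if (length(dim(coords)) == 3L) dim(coords) <- c(dim(coords), 1L)
  stopifnot(length(dim(coords)) == 4L, dim(coords)[2] == 3L)
  n_atoms <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  n_chains <- dim(coords)[4]

  atoms <- complete_atom_table(atoms)
  if (nrow(atoms) != n_atoms) {
    abort("`atoms` must have one row per atom in `coords`.")
  }
  if (is.null(times)) times <- seq_len(n_frames) - 1
  if (length(times) != n_frames || any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing with one entry per frame.")
  }
  if (!is.null(chains) && nrow(chains) != n_chains) {
    abort("`chains` must have one row per chain.")
  }
  if (!is.null(box)) {
    if (is.matrix(box)) box <- array(box, c(3, 3, n_frames))
    stopifnot(all(dim(box) == c(3, 3, n_frames)))
  }
  structure(
    list(coords = coords, atoms = atoms, times = as.numeric(times),
         replica = replica, chains = chains, box = box),
    class = "trajectory_ensemble"
  )
}

complete_atom_table <- function(atoms) {
  atoms <- as_tibble(atoms)
  req <- c("atom_name", "residue_index", "residue_name")
  missing <- setdiff(req, names(atoms))
  if (length(missing)) {
    abort(paste0("`atoms` lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"element" %in% names(atoms)) {
    atoms$element <- substr(gsub("[0-9]", "", atoms$atom_name), 1, 1)
  }
  if (!"mass" %in% names(atoms)) atoms$mass <- element_mass(atoms$element)
  if (!"is_heavy" %in% names(atoms)) atoms$is_heavy <- atoms$element != "H"
  if (!"is_ca" %in% names(atoms)) atoms$is_ca <- atoms$atom_name == "CA"
  atoms
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf(
    "<trajectory_ensemble> %d chain(s) x %d frame(s) x %d atoms (replica %s)\n",
    d[4], d[3], d[1], format(x$replica)))
  cat(sprintf("  residues: %d   time span: %.4g-%.4g ns\n",
              length(unique(x$atoms$residue_index)),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @rdname trajectory_ensemble
#' @param x,ens a `trajectory_ensemble`.
#' @export
n_chains <- function(ens) dim(ens$coords)[4]

#' @rdname trajectory_ensemble
#' @export
n_frames <- function(ens) dim(ens$coords)[3]

#' @rdname trajectory_ensemble
#' @export
n_atoms <- function(ens) dim(ens$coords)[1]

#' @rdname trajectory_ensemble
#' @param chain,frame 1-based chain and frame indices.
#' @export
chain_frame <- function(ens, chain, frame) {
  ens$coords[, , frame, chain, drop = TRUE]
}

#' @export
as_tibble.trajectory_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  grid <- tidyr::expand_grid(
    chain = seq_len(d[4]), frame = seq_len(d[3]), atom = seq_len(d[1])
  )
  ## coords is [atom, xyz, frame, chain]; expand in matching order
  co <- aperm(x$coords, c(1, 3, 4, 2))
  dim(co) <- c(d[1] * d[3] * d[4], 3)
  grid <- dplyr::arrange(grid, .data$chain, .data$frame, .data$atom)
  dplyr::bind_cols(
    grid,
    tibble(time_ns = x$times[grid$frame],
           x = co[cbind(grid$atom + (grid$frame - 1) * d[1] +
                          (grid$chain - 1) * d[1] * d[3], 1)],
           y = co[cbind(grid$atom + (grid$frame - 1) * d[1] +
                          (grid$chain - 1) * d[1] * d[3], 2)],
           z = co[cbind(grid$atom + (grid$frame - 1) * d[1] +
                          (grid$chain - 1) * d[1] * d[3], 3)])
  )
}

## atom selection helper: "all", "heavy", "calpha", or a logical/integer vector
atom_selection <- function(ens, selection) {
  if (is.character(selection)) {
    sel <- switch(selection,
      all = rep(TRUE, n_atoms(ens)),
      heavy = ens$atoms$is_heavy,
      calpha = ens$atoms$is_ca,
      abort(sprintf("unknown selection '%s' (use 'all', 'heavy', 'calpha')",
                    selection))
    )
    which(sel)
  } else if (is.logical(selection)) {
    which(selection)
  } else {
    as.integer(selection)
  }
}

## mass-weighted centre of mass of the heavy atoms of a coordinate matrix
mass_com <- function(coords, mass, heavy = NULL) {
  if (!is.null(heavy)) {
    coords <- coords[heavy, , drop = FALSE]
    mass <- mass[heavy]
  }
  colSums(coords * mass) / sum(mass)
}
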