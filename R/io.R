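#' Read a reference crystal structure from PDB
#'
#' Parses the CRYST1 record into a [unit_cell()] and splits the atoms into
#' protein and ordered-water (HOH/WAT) records.
#'
#' @param path path to a PDB file.
#' @return A list: `atoms` (protein metadata tibble), `coords`
#'   (protein, Angstrom), `cell` (a [unit_cell()] or `NULL` when no CRYST1
#'   record is present), `space_group` (trimmed CRYST1 field), and
#'   `waters` (`list(coords, b_exp)` for water oxygens).
#' @export
read_reference_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  cell <- NULL; sg <- NULL
  if (length(cr)) {
    cr <- cr[1]
    cell <- unit_cell(
      a = as.numeric(substr(cr, 7, 15)),
      b = as.numeric(substr(cr, 16, 24)),
      c = as.numeric(substr(cr, 25, 33)),
      alpha = as.numeric(substr(cr, 34, 40)),
      beta = as.numeric(substr(cr, 41, 47)),
      gamma = as.numeric(substr(cr, 48, 54))
    )
    sg <- trimws(substr(cr, 56, 66))
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  is_water <- at$resid %in% c("HOH", "WAT", "SOL")
  is_o <- at$elety %in% c("O", "OW", "OH2")
  prot <- at[!is_water, , drop = FALSE]
  wat <- at[is_water & is_o, , drop = FALSE]
  atoms <- complete_atom_table(tibble(
    atom_name = prot$elety, residue_index = prot$resno,
    residue_name = prot$resid
  ))
  list(
    atoms = atoms,
    coords = cbind(prot$x, prot$y, prot$z),
    cell = cell, space_group = sg,
    waters = list(coords = cbind(wat$x, wat$y, wat$z), b_exp = wat$b)
  )
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL becomes a frame; when several chain identifiers with
#' identical per-chain topology are present, chains become the ensemble's
#' chain dimension.
#'
#' @param path path to a multi-model PDB file.
#' @param times optional frame times in ns.
#' @param replica replica identifier.
#' @return A [trajectory_ensemble()].
#' @export
read_ensemble_pdb <- function(path, times = NULL, replica = 1L) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  xyz <- pdb$xyz                       # models x 3N
  nf <- nrow(xyz)
  na_tot <- nrow(at)
  co <- array(t(xyz), c(3, na_tot, nf))
  co <- aperm(co, c(2, 1, 3))          # atoms x 3 x frames

  chain_ids <- unique(at$chain)
  split_ok <- length(chain_ids) > 1 &&
    length(unique(table(at$chain))) == 1
  if (split_ok) {
    per <- split(seq_len(na_tot), at$chain)
    names_ok <- all(vapply(per, function(ix)
      identical(at$elety[ix], at$elety[per[[1]]]), logical(1)))
    split_ok <- names_ok
  }
  if (split_ok) {
    idx1 <- per[[1]]
    coords <- array(NA_real_, c(length(idx1), 3, nf, length(per)))
    for (ch in seq_along(per)) coords[, , , ch] <- co[per[[ch]], , ]
    atoms <- tibble(atom_name = at$elety[idx1],
                    residue_index = at$resno[idx1],
                    residue_name = at$resid[idx1])
  } else {
    coords <- array(co, c(na_tot, 3, nf, 1))
    atoms <- tibble(atom_name = at$elety, residue_index = at$resno,
                    residue_name = at$resid)
  }
  trajectory_ensemble(coords, atoms, times = times, replica = replica)
}

#' Write an ensemble as a multi-model PDB
#'
#' Chains are concatenated with cycling chain identifiers inside each
#' MODEL block.
#'
#' @param ens a [trajectory_ensemble()].
#' @param path output path.
#' @param cell optional [unit_cell()] written as a CRYST1 record.
#' @param space_group CRYST1 space-group field (default `"C 1 2 1"`).
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path, cell = NULL,
                               space_group = "C 1 2 1") {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cell)) {
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
      cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
      space_group, 1L), con)
  }
  ids <- c(LETTERS, letters, 0:9)
  at <- ens$atoms
  for (f in seq_len(n_frames(ens))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L
    for (ch in seq_len(n_chains(ens))) {
      xyz <- ens$coords[, , f, ch]
      cid <- ids[(ch - 1L) %% length(ids) + 1L]
      for (i in seq_len(nrow(at))) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, at$atom_name[i], at$residue_name[i], cid,
          at$residue_index[i], xyz[i, 1], xyz[i, 2], xyz[i, 3],
          1.0, 0.0, at$element[i]), con)
      }
      writeLines("TER", con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
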