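#' Per-residue thermal-deviation profile of an ensemble
#'
#' Samples random unordered pairs of structures (uniformly with
#' replacement, self-pairs excluded), superposes each pair on all shared
#' C-alpha atoms, and averages the per-residue C-alpha deviation over
#' pairs -- the pattern of where thermal motion moves the structure.
#'
#' @param structures list of `n_res x 3` C-alpha coordinate matrices, or a
#'   [trajectory_ensemble()] (every chain-frame is a structure; C-alpha
#'   atoms are extracted).
#' @param residues residue indices labelling the rows (defaults to the
#'   ensemble's C-alpha residues, else `1..n`).
#' @param n_pairs number of sampled pairs (default 2000).
#' @param seed RNG seed.
#' @return A `deviation_profile` tibble `residue, deviation` (Angstrom)
#'   with attribute `n_pairs`.
#' @export
ensemble_deviation_profile <- function(structures, residues = NULL,
                                       n_pairs = 2000, seed = 1) {
  if (inherits(structures, "trajectory_ensemble")) {
    ens <- structures
    ca <- which(ens$atoms$is_ca)
    if (is.null(residues)) residues <- ens$atoms$residue_index[ca]
    structures <- list()
    for (ch in seq_len(n_chains(ens))) {
      for (f in seq_len(n_frames(ens))) {
        structures[[length(structures) + 1L]] <- ens$coords[ca, , f, ch]
      }
    }
  }
  ns <- length(structures)
  if (ns < 2) abort("need at least 2 structures")
  nr <- nrow(structures[[1]])
  if (is.null(residues)) residues <- seq_len(nr)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  i <- sample.int(ns, n_pairs, replace = TRUE)
  j <- sample.int(ns, n_pairs, replace = TRUE)
  fix <- i == j
  while (any(fix)) {
    j[fix] <- sample.int(ns, sum(fix), replace = TRUE)
    fix <- i == j
  }
  acc <- numeric(nr)
  for (p in seq_len(n_pairs)) {
    fit <- kabsch_superpose(structures[[i[p]]], structures[[j[p]]])
    acc <- acc + sqrt(rowSums((fit$coords - structures[[j[p]]])^2))
  }
  out <- tibble(residue = residues, deviation = acc / n_pairs)
  class(out) <- c("deviation_profile", class(out))
  attr(out, "n_pairs") <- n_pairs
  out
}

#' Ligand-induced deviation profile from apo/holo structure pairs
#'
#' For each homolog pair the ligand-bound (holo) structure is superposed
#' onto the ligand-free (apo) one on all mapped C-alpha atoms; per-residue
#' deviations are averaged across pairs on the reference numbering.
#' Residues missing from some pairs are averaged over the pairs that
#' cover them; residues covered by no pair appear with `coverage = 0` and
#' `NA` deviation (never as zeros).
#'
#' @param pairs list of pairs, each a list with `apo` and `holo`
#'   (`m x 3` C-alpha matrices, row-aligned to each other) and `residues`
#'   (length-`m` integer vector mapping rows to reference numbering; the
#'   mapping is supplied explicitly, e.g. from a curated renumbering
#'   table, never inferred).
#' @param all_residues optional reference residue set to report (adds
#'   coverage-0 rows).
#' @return A `deviation_profile` tibble `residue, deviation, coverage`.
#' @export
ligand_induced_profile <- function(pairs, all_residues = NULL) {
  ok <- vapply(pairs, function(p) length(p$residues) >= 3, logical(1))
  if (!any(ok)) abort("no pair with at least 3 mapped residues")
  pairs <- pairs[ok]
  per <- purrr::map_dfr(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    stopifnot(nrow(p$apo) == nrow(p$holo),
              nrow(p$apo) == length(p$residues))
    fit <- kabsch_superpose(p$holo, p$apo)
    tibble(pair = k, residue = p$residues,
           deviation = sqrt(rowSums((fit$coords - p$apo)^2)))
  })
  out <- per %>%
    dplyr::group_by(.data$residue) %>%
    dplyr::summarise(deviation = mean(.data$deviation),
                     coverage = dplyr::n(), .groups = "drop")
  if (!is.null(all_residues)) {
    out <- dplyr::full_join(out, tibble(residue = all_residues),
                            by = "residue") %>%
      dplyr::mutate(coverage = dplyr::coalesce(.data$coverage, 0L)) %>%
      dplyr::arrange(.data$residue)
  }
  class(out) <- c("deviation_profile", class(out))
  out
}

#' Correlation between two deviation profiles
#'
#' Pearson correlation over the residues shared by both profiles,
#' quantifying the similarity between the thermal-motion pattern of a
#' simulated ensemble and, e.g., the ligand-induced deviation pattern of
#' homolog structure pairs.
#'
#' @param p1,p2 `deviation_profile` tibbles (columns `residue`,
#'   `deviation`).
#' @return A one-row tibble `r, n, p_value`.
#' @export
profile_correlation <- function(p1, p2) {
  j <- dplyr::inner_join(p1[c("residue", "deviation")],
                         p2[c("residue", "deviation")],
                         by = "residue", suffix = c("_1", "_2"))
  j <- j[is.finite(j$deviation_1) & is.finite(j$deviation_2), ]
  if (nrow(j) < 3) abort("need at least 3 shared residues with finite values")
  if (sd(j$deviation_1) == 0 || sd(j$deviation_2) == 0) {
    abort("constant profile: correlation undefined")
  }
  ct <- cor.test(j$deviation_1, j$deviation_2)
  tibble(r = unname(ct$estimate), n = nrow(j), p_value = ct$p.value)
}
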