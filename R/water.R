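#' Anchor crystallographic water sites to coordinating protein atoms
#'
#' For every ordered (crystallographic) water oxygen, the anchors are the
#' protein heavy atoms within `anchor_cutoff` in the reference structure.
#' Sites with fewer than `min_anchors` anchors cannot be tracked by local
#' alignment; they are flagged and excluded from preservation statistics.
#'
#' @param protein_coords `n_atoms x 3` reference protein coordinates.
#' @param atoms protein atom metadata (see [trajectory_ensemble()]).
#' @param water_coords `n_waters x 3` water-oxygen coordinates.
#' @param anchor_cutoff anchor distance cutoff in Angstrom (default 4.0).
#' @param min_anchors minimum anchors required (default 3).
#' @param b_exp optional per-water experimental B-factors (Angstrom^2).
#' @return A tibble `site_id, x, y, z, n_anchors, anchors (list of atom
#'   indices), b_exp, flagged` of class `water_sites`.
#' @export
anchor_cws <- function(protein_coords, atoms, water_coords,
                       anchor_cutoff = 4.0, min_anchors = 3, b_exp = NULL) {
  water_coords <- rbind(water_coords)
  if (nrow(water_coords) == 0) abort("no waters in reference")
  atoms <- complete_atom_table(atoms)
  hv <- which(atoms$is_heavy)
  ph <- protein_coords[hv, , drop = FALSE]
  if (is.null(b_exp)) b_exp <- rep(NA_real_, nrow(water_coords))

  out <- purrr::map_dfr(seq_len(nrow(water_coords)), function(i) {
    d <- sqrt(colSums((t(ph) - water_coords[i, ])^2))
    anchor_idx <- hv[d <= anchor_cutoff]
    anchor_xyz <- protein_coords[anchor_idx, , drop = FALSE]
    tibble(site_id = i,
           x = water_coords[i, 1], y = water_coords[i, 2],
           z = water_coords[i, 3],
           n_anchors = length(anchor_idx), anchors = list(anchor_idx),
           ref_anchor_coords = list(anchor_xyz),
           b_exp = b_exp[i], flagged = length(anchor_idx) < min_anchors)
  })
  class(out) <- c("water_sites", class(out))
  attr(out, "anchor_cutoff") <- anchor_cutoff
  attr(out, "min_anchors") <- min_anchors
  out
}

#' Track water-site occupancy through a trajectory
#'
#' Local-alignment tracking: per frame, each site's anchor atoms are
#' least-squares superposed onto their reference positions; the inverse of
#' that transform carries the reference site into the frame, and the site
#' is occupied when any water oxygen lies within `occupancy_radius` of the
#' transformed position (minimum-image convention when box vectors are
#' given).
#'
#' @param protein_traj `n_atoms x 3 x n_frames` protein coordinates (one
#'   chain).
#' @param sites a `water_sites` table from [anchor_cws()] (built on the
#'   same protein topology).
#' @param waters list (length `n_frames`) of water-oxygen coordinate
#'   matrices (possibly zero-row).
#' @param occupancy_radius in Angstrom (default 1.4, roughly the radius
#'   of a water-oxygen density peak).
#' @param box optional 3x3 cell matrix (or `3 x 3 x n_frames` array) for
#'   minimum-image distances.
#' @return A tibble `site_id, frame, occupied` (flagged sites excluded).
#' @export
track_cws <- function(protein_traj, sites, waters, occupancy_radius = 1.4,
                      box = NULL) {
  if (length(dim(protein_traj)) == 2L) {
    dim(protein_traj) <- c(dim(protein_traj), 1L)
  }
  nf <- dim(protein_traj)[3]
  if (length(waters) != nf) abort("`waters` must have one entry per frame")
  keep <- sites[!sites$flagged, ]
  if (max(unlist(keep$anchors)) > dim(protein_traj)[1]) {
    abort("anchor atoms missing from trajectory topology")
  }
  if (!is.null(box) && is.matrix(box)) box <- array(box, c(3, 3, nf))

  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    w <- rbind(waters[[f]])
    occ <- logical(nrow(keep))
    for (s in seq_len(nrow(keep))) {
      idx <- keep$anchors[[s]]
      ref_anchor <- cbind(keep$ref_anchor_coords[[s]])
      cur_anchor <- protein_traj[idx, , f, drop = TRUE]
      ## transform carrying reference frame -> current frame
      fit <- kabsch_superpose(ref_anchor, cur_anchor,
                              seq_len(nrow(ref_anchor)))
      site_now <- as.numeric(
        fit$rotation %*% c(keep$x[s], keep$y[s], keep$z[s]) +
          fit$translation)
      if (nrow(w) == 0 || is.null(w)) { occ[s] <- FALSE; next }
      dv <- sweep(w, 2, site_now)
      if (!is.null(box)) dv <- minimum_image(dv, box[, , f])
      occ[s] <- min(rowSums(dv^2)) <= occupancy_radius^2
    }
    out[[f]] <- tibble(site_id = keep$site_id, frame = f, occupied = occ)
  }
  dplyr::bind_rows(out)
}

minimum_image <- function(dv, cell) {
  fr <- dv %*% t(solve(cell))
  fr <- fr - round(fr)
  fr %*% t(cell)
}

#' Per-site occupancy fractions
#'
#' @param tracked tibble from [track_cws()] (optionally with a `replica`
#'   column).
#' @return Tibble `site_id (, replica), occupancy, n_frames`.
#' @export
site_occupancy <- function(tracked) {
  grp <- intersect(c("site_id", "replica"), names(tracked))
  tracked %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::summarise(occupancy = mean(.data$occupied),
                     n_frames = dplyr::n(), .groups = "drop")
}

#' Preservation summary of crystallographic water sites
#'
#' A site is preserved when its occupancy is at least `occ_threshold`.
#' Reports the overall preserved fraction (with a between-replica standard
#' deviation when replicas are present) and the fraction per
#' experimental-B-factor bin -- well-ordered (low-B) sites are expected to
#' be preserved more often than marginal ones.
#'
#' @param tracked tibble from [track_cws()], or a per-site occupancy table
#'   from [site_occupancy()].
#' @param sites the `water_sites` table (for `b_exp`).
#' @param occ_threshold preservation threshold on occupancy (default 0.5).
#' @param b_breaks breaks for the experimental-B bins; defaults to
#'   tertiles of the available `b_exp`.
#' @return A list: one-row `overall` tibble (`fraction, sd, n_sites`),
#'   `per_replica`, `by_b` (fractions per B bin), and the per-site table.
#' @export
preservation_summary <- function(tracked, sites, occ_threshold = 0.5,
                                 b_breaks = NULL) {
  if (nrow(tracked) == 0) abort("empty occupancy input")
  occ <- if ("occupied" %in% names(tracked)) site_occupancy(tracked)
         else tracked
  occ$preserved <- occ$occupancy >= occ_threshold
  occ <- dplyr::left_join(occ, sites[c("site_id", "b_exp")], by = "site_id")
  if (!"replica" %in% names(occ)) occ$replica <- 1L

  per_replica <- occ %>%
    dplyr::group_by(.data$replica) %>%
    dplyr::summarise(fraction = mean(.data$preserved), .groups = "drop")
  overall <- tibble(
    fraction = mean(per_replica$fraction),
    sd = if (nrow(per_replica) > 1) sd(per_replica$fraction) else NA_real_,
    n_sites = length(unique(occ$site_id))
  )
  by_b <- NULL
  if (any(is.finite(occ$b_exp))) {
    if (is.null(b_breaks)) {
      b_breaks <- unique(quantile(occ$b_exp, c(0, 1/3, 2/3, 1),
                                  na.rm = TRUE))
      if (length(b_breaks) < 2) b_breaks <- c(-Inf, Inf)
    }
    by_b <- occ %>%
      dplyr::filter(is.finite(.data$b_exp)) %>%
      dplyr::mutate(b_bin = cut(.data$b_exp, breaks = b_breaks,
                                include.lowest = TRUE)) %>%
      dplyr::group_by(.data$b_bin) %>%
      dplyr::summarise(fraction = mean(.data$preserved),
                       n_sites = dplyr::n(), .groups = "drop")
  }
  list(overall = overall, per_replica = per_replica, by_b = by_b,
       sites = occ)
}
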