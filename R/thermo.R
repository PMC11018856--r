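#' Residue-pair distance series
#'
#' Euclidean distance between one atom of each of two residues, per chain
#' and frame. An internal coordinate: no alignment is applied or needed.
#'
#' @param ens a [trajectory_ensemble()].
#' @param res_i,res_j residue indices (e.g. the loop-clamping pair
#'   Ser14-Gly78 of a PDZ domain).
#' @param atom atom name used in both residues (default `"CA"`).
#' @return A tibble `chain, frame, time_ns, distance` (Angstrom).
#' @export
distance_series <- function(ens, res_i, res_j, atom = "CA") {
  ai <- which(ens$atoms$residue_index == res_i & ens$atoms$atom_name == atom)
  aj <- which(ens$atoms$residue_index == res_j & ens$atoms$atom_name == atom)
  if (length(ai) != 1 || length(aj) != 1) {
    abort(sprintf("atom %s of residue %d/%d missing from topology",
                  atom, res_i, res_j))
  }
  nf <- n_frames(ens); nc <- n_chains(ens)
  grid <- tidyr::expand_grid(chain = seq_len(nc), frame = seq_len(nf))
  d <- sqrt(
    (ens$coords[ai, 1, , ] - ens$coords[aj, 1, , ])^2 +
    (ens$coords[ai, 2, , ] - ens$coords[aj, 2, , ])^2 +
    (ens$coords[ai, 3, , ] - ens$coords[aj, 3, , ])^2
  )
  d <- matrix(d, nf, nc)          # [frame, chain]
  tibble(chain = grid$chain, frame = grid$frame,
         time_ns = ens$times[grid$frame],
         distance = d[cbind(grid$frame, grid$chain)])
}

#' Binned probability distribution with chain-level bootstrap errors
#'
#' Histogram estimator of a distance distribution on uniform bins, with
#' standard errors from bootstrap resampling of whole chains (frames
#' within a chain are autocorrelated; chains are the independent unit).
#' Without chain structure, frames are resampled instead.
#'
#' @param samples numeric vector of distances (Angstrom), or a tibble with
#'   `distance` and optionally `chain` columns (e.g. from
#'   [distance_series()]).
#' @param n_bins number of bins (default 50).
#' @param range bin range in Angstrom (default `c(2, 18)`, giving the
#'   standard 0.32 A bin width). Out-of-range samples are counted,
#'   reported via attribute `n_out_of_range`, and excluded from the
#'   masses.
#' @param n_boot bootstrap resamples (default 5).
#' @param seed RNG seed for the bootstrap.
#' @return A `distance_distribution`: tibble `lower, upper, center, p, se`
#'   whose masses sum to 1, with attributes `n`, `n_out_of_range`,
#'   `bin_width`, `n_boot`, `edges`.
#' @export
histogram_distribution <- function(samples, n_bins = 50, range = c(2, 18),
                                   n_boot = 5, seed = 1) {
  if (is.data.frame(samples)) {
    chain <- if ("chain" %in% names(samples)) samples$chain else NULL
    xs <- samples$distance
  } else {
    chain <- NULL
    xs <- as.numeric(samples)
  }
  if (length(xs) == 0) abort("empty sample set")
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  width <- diff(range) / n_bins

  mass <- function(v) {
    inr <- v >= range[1] & v <= range[2]
    h <- tabulate(pmin(pmax(ceiling((v[inr] - range[1]) / width), 1L),
                       n_bins), nbins = n_bins)
    if (sum(h) == 0) rep(0, n_bins) else h / sum(h)
  }
  p <- mass(xs)
  if (all(p == 0)) abort("no samples inside the histogram range")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boot <- replicate(n_boot, {
    if (!is.null(chain)) {
      ids <- unique(chain)
      pick <- sample(ids, length(ids), replace = TRUE)
      mass(unlist(lapply(pick, function(id) xs[chain == id]),
                  use.names = FALSE))
    } else {
      mass(sample(xs, length(xs), replace = TRUE))
    }
  })
  se <- apply(boot, 1, sd)

  out <- tibble(lower = edges[-length(edges)], upper = edges[-1],
                center = (edges[-1] + edges[-length(edges)]) / 2,
                p = p, se = se)
  class(out) <- c("distance_distribution", class(out))
  attr(out, "n") <- sum(xs >= range[1] & xs <= range[2])
  attr(out, "n_out_of_range") <- sum(xs < range[1] | xs > range[2])
  attr(out, "bin_width") <- width
  attr(out, "n_boot") <- n_boot
  attr(out, "edges") <- edges
  out
}

#' Free-energy profile from a binned distribution
#'
#' `G_i = -ln p_i` in units of kBT (optionally kcal/mol at temperature
#' `T`), shifted so the minimum over occupied bins is zero. Empty bins are
#' undefined (`NA`), not zero. Errors are propagated as
#' `dG_i = dp_i / p_i`.
#'
#' @param dist a `distance_distribution`.
#' @param temperature temperature in K for the kcal/mol column (default
#'   289 K, a typical crystal-simulation temperature).
#' @return A `free_energy_profile`: tibble `center, p, g_kt, g_se,
#'   g_kcal_mol` with attribute `temperature`.
#' @export
free_energy_profile <- function(dist, temperature = 289) {
  if (all(dist$p <= 0)) abort("all-zero distribution")
  g <- ifelse(dist$p > 0, -log(dist$p), NA_real_)
  g <- g - min(g, na.rm = TRUE)
  kbt_kcal <- 0.0019872041 * temperature    # kB in kcal/mol/K
  out <- tibble(center = dist$center, p = dist$p,
                g_kt = g,
                g_se = ifelse(dist$p > 0, dist$se / dist$p, NA_real_),
                g_kcal_mol = g * kbt_kcal)
  class(out) <- c("free_energy_profile", class(out))
  attr(out, "temperature") <- temperature
  out
}

#' Shannon entropy of a binned distribution
#'
#' `S = -sum_i p_i ln p_i` over occupied bins (natural-log units). The
#' absolute value depends on the number of bins, which is recorded in the
#' `n_bins` attribute; comparisons are only meaningful at a fixed binning.
#'
#' @param dist a `distance_distribution` (or bare probability vector).
#' @return Scalar entropy with attribute `n_bins`.
#' @export
shannon_entropy <- function(dist) {
  p <- if (is.data.frame(dist)) dist$p else as.numeric(dist)
  p <- p[p > 0]
  structure(-sum(p * log(p)), n_bins = if (is.data.frame(dist))
    nrow(dist) else length(dist))
}

#' Default three-state definition of a loop-distance coordinate
#'
#' Closed below 6.5 A, intermediate in `[6.5, 10)` A, open at or above
#' 10 A -- a transparent interval fallback for the clustering-derived
#' open/intermediate/closed states of a loop coordinate.
#'
#' @return A tibble `state, lower, upper` partitioning the real line.
#' @export
loop_state_definition <- function() {
  tibble(state = c("closed", "intermediate", "open"),
         lower = c(-Inf, 6.5, 10), upper = c(6.5, 10, Inf))
}

#' State populations of a distance coordinate
#'
#' Assigns each sample to a named state (interval rule: lower-inclusive,
#' upper-exclusive) and reports the population of each state with a
#' chain-level bootstrap standard error. Alternatively, `samples` may be a
#' vector/column of pre-assigned state labels (e.g. from an external
#' embedding-space clustering), in which case `states` only fixes the
#' reporting order.
#'
#' @param samples numeric vector, or tibble with `distance` (or `state`
#'   for the label mode) and optional `chain`.
#' @param states interval rules as in [loop_state_definition()] (the
#'   default); must partition the samples (a sample outside all intervals
#'   is an error).
#' @param n_boot,seed bootstrap settings, as in
#'   [histogram_distribution()].
#' @return A tibble `state, population, se`.
#' @export
state_populations <- function(samples, states = loop_state_definition(),
                              n_boot = 5, seed = 1) {
  if (is.data.frame(samples) && !"distance" %in% names(samples) &&
        "state" %in% names(samples)) {
    ## pre-assigned labels (e.g. from an external clustering)
    labels <- as.character(samples$state)
    chain <- if ("chain" %in% names(samples)) samples$chain else NULL
    lev <- if ("state" %in% names(states) &&
                 all(labels %in% states$state)) states$state
           else sort(unique(labels))
  } else {
    if (is.data.frame(samples)) {
      xs <- samples$distance
      chain <- if ("chain" %in% names(samples)) samples$chain else NULL
    } else {
      xs <- as.numeric(samples); chain <- NULL
    }
    labels <- assign_states(xs, states)
    lev <- states$state
  }
  if (length(labels) == 0) abort("empty sample set")

  pops <- function(lab) {
    tab <- table(factor(lab, levels = lev))
    as.numeric(tab) / length(lab)
  }
  p <- pops(labels)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boot <- replicate(n_boot, {
    if (!is.null(chain)) {
      ids <- unique(chain)
      pick <- sample(ids, length(ids), replace = TRUE)
      pops(unlist(lapply(pick, function(id) labels[chain == id]),
                  use.names = FALSE))
    } else {
      pops(sample(labels, length(labels), replace = TRUE))
    }
  })
  tibble(state = lev, population = p, se = apply(boot, 1, sd))
}

assign_states <- function(x, states) {
  out <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(states))) {
    out[x >= states$lower[i] & x < states$upper[i]] <- states$state[i]
  }
  if (anyNA(out)) {
    abort(sprintf("%d sample(s) fall outside all state intervals; rules must partition",
                  sum(is.na(out))))
  }
  out
}
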