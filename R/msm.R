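#' Microstate clustering of projected coordinates
#'
#' k-means clustering of pooled projected coordinates, deterministic for a
#' fixed seed; each frame is assigned to its nearest centre (ties to the
#' lowest centre index).
#'
#' @param x a numeric matrix (one trajectory) or list of matrices (one per
#'   trajectory), rows = frames.
#' @param k number of microstates.
#' @param seed RNG seed.
#' @return A list: `dtrajs` (list of integer state sequences, states
#'   `1..k`), `centers`, `k`.
#' @export
cluster_microstates <- function(x, k, seed = 1) {
  if (is.matrix(x) || is.data.frame(x)) x <- list(as.matrix(x))
  x <- lapply(x, function(m) {
    m <- as.matrix(m)
    if (!all(is.finite(m))) abort("non-finite coordinates")
    m
  })
  pool <- do.call(rbind, x)
  if (k < 1) abort("k must be >= 1")
  if (nrow(unique(pool)) < k) abort("k exceeds the number of distinct points")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  centers <- if (k == 1) {
    matrix(colMeans(pool), nrow = 1)
  } else {
    stats::kmeans(pool, centers = k, nstart = 5, iter.max = 100)$centers
  }
  assign_fn <- function(m) nearest_center(m, centers)
  list(dtrajs = lapply(x, assign_fn), centers = centers, k = k)
}

nearest_center <- function(m, centers) {
  d2 <- outer(rowSums(m^2), rep(1, nrow(centers))) -
    2 * m %*% t(centers) +
    outer(rep(1, nrow(m)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

#' Transition counts at a lag
#'
#' Sliding-window counts of `(t, t + lag)` state pairs, accumulated per
#' trajectory and never across trajectory boundaries.
#'
#' @param dtrajs list of integer state sequences (states `1..n`), or a
#'   single vector.
#' @param lag lag in frames (>= 1, shorter than the longest trajectory).
#' @param n_states number of states (default: the maximum observed).
#' @return `n x n` count matrix `C[i, j]`.
#' @export
transition_counts <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  if (lag < 1) abort("lag must be >= 1")
  if (lag >= max(lengths(dtrajs))) abort("lag >= longest trajectory")
  if (is.null(n_states)) n_states <- max(unlist(dtrajs))
  counts <- matrix(0, n_states, n_states)
  for (dt in dtrajs) {
    len <- length(dt)
    if (len <= lag) next
    from <- dt[seq_len(len - lag)]
    to <- dt[seq_len(len - lag) + lag]
    tab <- table(factor(from, levels = seq_len(n_states)),
                 factor(to, levels = seq_len(n_states)))
    counts <- counts + unclass(tab)
  }
  dimnames(counts) <- NULL
  counts
}

#' Maximum-likelihood transition matrix and its spectrum
#'
#' Row-normalizes the count matrix (after trimming states with no counts)
#' into a row-stochastic transition matrix, and derives its eigenvalue
#' spectrum, stationary distribution and implied timescales
#' `t_i = -tau / ln(lambda_i)`. The reversible option symmetrizes counts
#' as `(C + C') / 2` before normalizing, which enforces detailed balance.
#'
#' @param counts count matrix from [transition_counts()].
#' @param reversible symmetrize counts first (default `FALSE`).
#' @param lag_frames,dt_ns lag in frames and the frame interval in ns
#'   (their product is the lag time used for timescales).
#' @return A `transition_model`: list with `transition_matrix`,
#'   `eigenvalues` (sorted, leading = 1), `stationary` (`pi`),
#'   `timescales` tibble (`index, eigenvalue, timescale_ns`; infinite with
#'   a warning when an eigenvalue reaches 1), `states` (original labels of
#'   the kept states), `trimmed`, `lag_frames`, `lag_ns`, `counts`.
#' @export
estimate_transition_matrix <- function(counts, reversible = FALSE,
                                       lag_frames = 1, dt_ns = 1) {
  n0 <- nrow(counts)
  keep <- which(rowSums(counts) + colSums(counts) > 0)
  ## states never left cannot be row-normalized: drop iteratively
  repeat {
    sub <- counts[keep, keep, drop = FALSE]
    bad <- keep[rowSums(sub) == 0]
    if (!length(bad)) break
    keep <- setdiff(keep, bad)
    if (!length(keep)) abort("no states with outgoing counts")
  }
  trimmed <- setdiff(seq_len(n0), keep)
  c_eff <- counts[keep, keep, drop = FALSE]

  ## a purely diagonal count matrix (no observed transitions) is allowed:
  ## it estimates the identity chain, whose timescales are infinite
  off_diag <- c_eff; diag(off_diag) <- 0
  comps <- if (all(off_diag == 0)) list(seq_len(nrow(c_eff)))
           else closed_communicating_sets(c_eff)
  if (length(comps) > 1) {
    abort(paste0("count graph has ", length(comps),
                 " closed communicating sets: ",
                 paste(vapply(comps, function(s)
                   paste0("{", paste(keep[s], collapse = ","), "}"),
                   character(1)), collapse = " ")))
  }

  if (reversible) c_eff <- (c_eff + t(c_eff)) / 2
  tm <- c_eff / rowSums(c_eff)

  ev <- eigen(tm)
  if (any(abs(Im(ev$values)) > 1e-8)) {
    warn("complex eigenvalues present; reporting real parts")
  }
  lam <- Re(ev$values)
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]

  lev <- eigen(t(tm))
  i1 <- which.min(abs(lev$values - 1))
  pi_ <- abs(Re(lev$vectors[, i1]))
  pi_ <- pi_ / sum(pi_)

  lag_ns <- lag_frames * dt_ns
  ts <- rep(NA_real_, length(lam))
  fin <- lam > 0 & lam < 1
  ts[fin] <- -lag_ns / log(lam[fin])
  if (length(lam) > 1 && any(lam[-1] >= 1 - 1e-12)) {
    warn("non-leading eigenvalue at 1: implied timescale infinite")
    ts[-1][lam[-1] >= 1 - 1e-12] <- Inf
  }
  timescales <- tibble(index = seq_along(lam), eigenvalue = lam,
                       timescale_ns = ts)[-1, ]

  structure(
    list(transition_matrix = tm, counts = c_eff,
         eigenvalues = lam, stationary = pi_,
         right_eigenvectors = Re(ev$vectors[, ord, drop = FALSE]),
         timescales = timescales, states = keep, trimmed = trimmed,
         reversible = reversible,
         lag_frames = lag_frames, dt_ns = dt_ns, lag_ns = lag_ns),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> %d states, lag %g ns%s\n",
              nrow(x$transition_matrix), x$lag_ns,
              if (x$reversible) " (reversible)" else ""))
  t2 <- x$timescales$timescale_ns[1]
  if (length(t2)) cat(sprintf("  slowest implied timescale: %.4g ns\n", t2))
  invisible(x)
}

## closed communicating classes of the count graph (states = rows)
closed_communicating_sets <- function(counts) {
  n <- nrow(counts)
  adj <- counts > 0
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  scc_id <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (scc_id[i] == 0L) {
      cur <- cur + 1L
      scc_id[reach[i, ] & reach[, i]] <- cur
    }
  }
  comps <- split(seq_len(n), scc_id)
  is_closed <- vapply(comps, function(s) {
    !any(counts[s, setdiff(seq_len(n), s), drop = FALSE] > 0)
  }, logical(1))
  comps[is_closed]
}

#' Implied timescales across lags
#'
#' Recomputes the transition-matrix spectrum for each lag and reports
#' `t_i(tau) = -tau / ln(lambda_i(tau))` together with a flatness
#' diagnostic (relative change between successive lags), the standard aid
#' for choosing a Markovian lag time.
#'
#' @inheritParams transition_counts
#' @param lags integer vector of >= 2 lags (frames).
#' @param dt_ns frame interval in ns.
#' @param n_timescales number of (non-stationary) timescales reported.
#' @param reversible passed to [estimate_transition_matrix()].
#' @return A tibble `lag_frames, lag_ns, index, eigenvalue, timescale_ns,
#'   rel_change`.
#' @export
implied_timescale_scan <- function(dtrajs, lags, dt_ns = 1,
                                   n_timescales = 2, reversible = FALSE) {
  if (length(lags) < 2) abort("need at least 2 lags")
  out <- purrr::map_dfr(sort(lags), function(l) {
    model <- estimate_transition_matrix(
      transition_counts(dtrajs, l), reversible = reversible,
      lag_frames = l, dt_ns = dt_ns)
    ts <- head(model$timescales, n_timescales)
    dplyr::mutate(ts, lag_frames = l, lag_ns = l * dt_ns,
                  .before = 1)
  })
  out %>%
    dplyr::group_by(.data$index) %>%
    dplyr::arrange(.data$lag_frames, .by_group = TRUE) %>%
    dplyr::mutate(rel_change = abs(.data$timescale_ns -
                                     dplyr::lag(.data$timescale_ns)) /
                    dplyr::lag(.data$timescale_ns)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$lag_frames, .data$index)
}

#' Spectral (PCCA-style) coarse-graining into metastable macrostates
#'
#' Crisp kinetic lumping: microstates are grouped by the simplex/sign
#' structure of the leading `n_macro` right eigenvectors of the transition
#' matrix (k-means on the eigenvector rows), a simplification of PCCA+
#' that reproduces the macrostate assignment on metastable systems. The
#' macrostate transition matrix is re-counted on the lumped trajectories
#' at the same lag when `dtrajs` are supplied, and aggregated from the
#' stationary-weighted microstate matrix otherwise.
#'
#' @param model a `transition_model`.
#' @param n_macro number of macrostates (must not cut through a degenerate
#'   eigenvalue pair).
#' @param dtrajs optional discrete trajectories (original state labels)
#'   for re-counting the macro transition matrix.
#' @param seed seed for the deterministic eigenvector clustering.
#' @return A `coarse_graining`: list with `assignment` (micro -> macro,
#'   labelled in order of first appearance), `n_macro`,
#'   `macro_transition_matrix`, `macro_populations` (summed stationary
#'   weights), and the micro `stationary` vector.
#' @export
pcca_coarse_grain <- function(model, n_macro, dtrajs = NULL, seed = 1) {
  lam <- model$eigenvalues
  n <- length(lam)
  if (n_macro > sum(lam > 0)) {
    abort("n_macro exceeds the number of positive eigenvalues")
  }
  if (n_macro < n && abs(lam[n_macro] - lam[n_macro + 1]) < 1e-10) {
    abort("degenerate eigenvalues at the cut; choose a different n_macro")
  }
  ev <- model$right_eigenvectors[, seq_len(n_macro), drop = FALSE]

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cl <- if (n_macro == n) {
    seq_len(n)
  } else if (n_macro == 1) {
    rep(1L, n)
  } else {
    stats::kmeans(ev, centers = n_macro, nstart = 20, iter.max = 100)$cluster
  }
  ## relabel macrostates by first appearance for determinism
  relabel <- match(cl, unique(cl))

  pi_ <- model$stationary
  pops <- as.numeric(tapply(pi_, relabel, sum))

  if (!is.null(dtrajs)) {
    if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
    ## map original state labels through the kept-state index
    lookup <- rep(NA_integer_, max(model$states))
    lookup[model$states] <- relabel
    lumped <- lapply(dtrajs, function(dt) lookup[dt])
    if (anyNA(unlist(lumped))) {
      lumped <- lapply(lumped, function(v) v[!is.na(v)])
    }
    mc <- transition_counts(lumped, model$lag_frames, n_states = n_macro)
    macro_t <- mc / rowSums(mc)
  } else {
    macro_t <- matrix(0, n_macro, n_macro)
    for (a in seq_len(n_macro)) {
      ia <- which(relabel == a)
      wa <- pi_[ia] / sum(pi_[ia])
      for (b in seq_len(n_macro)) {
        ib <- which(relabel == b)
        macro_t[a, b] <- sum(wa * rowSums(
          model$transition_matrix[ia, ib, drop = FALSE]))
      }
    }
  }
  structure(
    list(assignment = relabel, n_macro = n_macro,
         macro_transition_matrix = macro_t,
         macro_populations = pops, stationary = pi_),
    class = "coarse_graining"
  )
}

#' @export
print.coarse_graining <- function(x, ...) {
  cat(sprintf("<coarse_graining> %d macrostates; populations: %s\n",
              x$n_macro,
              paste(sprintf("%.3f", x$macro_populations), collapse = ", ")))
  invisible(x)
}

#' Cross-validated eigenvalue (GMRQ-style) score
#'
#' Trajectory-wise cross-validation of a microstate decomposition: centres
#' are fitted on the training trajectories, held-out trajectories are
#' assigned to those centres, and the score of a fold is the sum of the
#' leading `m` eigenvalues of the held-out transition matrix. Larger
#' scores indicate state definitions that better capture slow dynamics;
#' the score never exceeds `m`.
#'
#' @param x list of projected-coordinate matrices, one per trajectory
#'   (>= `n_folds` trajectories).
#' @param k number of microstates.
#' @param lag lag in frames.
#' @param n_folds number of folds (>= 2), split by trajectory.
#' @param m number of eigenvalues summed (default 2).
#' @param seed RNG seed (fold assignment and clustering).
#' @return A one-row tibble `score, se, n_folds, k, lag` with the
#'   per-fold table as attribute `folds`.
#' @export
gmrq_cv_score <- function(x, k, lag, n_folds = 5, m = 2, seed = 1) {
  if (!is.list(x)) abort("`x` must be a list of trajectories")
  nt <- length(x)
  if (n_folds < 2) abort("n_folds must be >= 2")
  if (nt < n_folds) abort("need at least one trajectory per fold")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_id <- sample(rep(seq_len(n_folds), length.out = nt))

  scores <- vapply(seq_len(n_folds), function(fd) {
    train <- x[fold_id != fd]
    test <- x[fold_id == fd]
    cl <- cluster_microstates(train, k, seed = seed + fd)
    dt_test <- lapply(test, function(m_) nearest_center(as.matrix(m_),
                                                        cl$centers))
    counts <- transition_counts(dt_test, lag, n_states = k)
    keep <- which(rowSums(counts) > 0 & colSums(counts) > 0)
    counts <- counts[keep, keep, drop = FALSE]
    tmat <- counts / rowSums(counts)
    lam <- sort(Re(eigen(tmat, only.values = TRUE)$values),
                decreasing = TRUE)
    sum(head(lam, m))
  }, numeric(1))

  out <- tibble(score = mean(scores), se = sd(scores) / sqrt(n_folds),
                n_folds = n_folds, k = k, lag = lag, m = m)
  attr(out, "folds") <- tibble(fold = seq_len(n_folds), score = scores)
  out
}
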