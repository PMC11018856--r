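#' Tidy a projection model
#'
#' Loadings in long form: one row per feature and component.
#'
#' @param x a `projection_model`.
#' @param ... unused.
#' @return A tibble `feature, component, loading`.
#' @export
tidy.projection_model <- function(x, ...) {
  load <- x$loadings
  purrr::map_dfr(seq_len(ncol(load)), function(i) {
    tibble(feature = x$features, component = i, loading = load[, i])
  })
}

#' @rdname tidy.projection_model
#' @export
glance.projection_model <- function(x, ...) {
  tibble(kind = x$kind,
         n_components = ncol(x$loadings),
         explained_variance = sum(x$explained_variance),
         ev1 = x$explained_variance[1],
         ev2 = if (length(x$explained_variance) > 1)
           x$explained_variance[2] else NA_real_)
}

#' Tidy a transition model
#'
#' @param x a `transition_model`.
#' @param ... unused.
#' @return The implied-timescale tibble `index, eigenvalue, timescale_ns`.
#' @export
tidy.transition_model <- function(x, ...) x$timescales

#' @rdname tidy.transition_model
#' @export
glance.transition_model <- function(x, ...) {
  tibble(n_states = nrow(x$transition_matrix),
         lag_ns = x$lag_ns,
         reversible = x$reversible,
         t2_ns = x$timescales$timescale_ns[1],
         n_trimmed = length(x$trimmed))
}

#' Tidy a covariance-decay fit
#'
#' @param x a `covariance_decay`.
#' @param ... unused.
#' @return The distance-bin tibble `center, mean_cov, n_pairs, fitted`.
#' @export
tidy.covariance_decay <- function(x, ...) x$bins

#' @rdname tidy.covariance_decay
#' @export
glance.covariance_decay <- function(x, ...) {
  tibble(amplitude = x$amplitude, decay_length = x$decay_length,
         method = x$method, degenerate = x$degenerate,
         naive_decay_length = x$naive$decay_length)
}

#' Tidy an equilibration report
#'
#' @param x an `equilibration_report`.
#' @param ... unused.
#' @return The per-replica tibble.
#' @export
tidy.equilibration_report <- function(x, ...) x$replicas

#' @rdname tidy.equilibration_report
#' @export
glance.equilibration_report <- function(x, ...) {
  tibble(condition_plateau = x$condition_plateau,
         condition_agreement = x$condition_agreement,
         equilibrated = x$equilibrated)
}

#' Tidy a coarse-grained Markov model
#'
#' @param x a `coarse_graining`.
#' @param ... unused.
#' @return A tibble `macrostate, population, n_micro`.
#' @export
tidy.coarse_graining <- function(x, ...) {
  tibble(macrostate = seq_len(x$n_macro),
         population = x$macro_populations,
         n_micro = as.integer(table(factor(x$assignment,
                                           levels = seq_len(x$n_macro)))))
}
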