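#' Principal component analysis of a feature matrix
#'
#' Mean-centred (unscaled) PCA via the thin singular value decomposition.
#' Components are ordered by explained variance; projections are
#' reproducible bit-for-bit for a fixed input order.
#'
#' @param fm a `feature_matrix` (see [featurize_sincos()],
#'   [featurize_ca_distances()]).
#' @param n_components number of components retained (default 2).
#' @return A `projection_model` (kind `"pca"`): list with `mean`,
#'   `loadings` (features x k, orthonormal), `explained_variance`
#'   (fractions of total variance, non-increasing), `scores` tibble
#'   (sample metadata + `PC1..PCk`), and `top_loadings` (the
#'   largest-magnitude loadings per component, for attributing components
#'   to residues).
#' @export
pca_fit <- function(fm, n_components = 2) {
  x <- fm$x
  if (all(abs(sweep(x, 2, colMeans(x))) < 1e-300)) {
    abort("zero-variance input: all samples identical")
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pr$sdev^2)
  if (total_var <= 0) abort("zero-variance input")
  k <- min(n_components, ncol(pr$rotation))
  scores <- as_tibble(pr$x[, seq_len(k), drop = FALSE],
                      .name_repair = "minimal")
  names(scores) <- paste0("PC", seq_len(k))
  load <- pr$rotation[, seq_len(k), drop = FALSE]
  top <- purrr::map_dfr(seq_len(k), function(i) {
    o <- order(abs(load[, i]), decreasing = TRUE)[seq_len(min(10, nrow(load)))]
    tibble(component = i, feature = fm$features[o], loading = load[o, i])
  })
  structure(
    list(kind = "pca", mean = pr$center, loadings = load,
         sdev = pr$sdev[seq_len(k)],
         explained_variance = pr$sdev[seq_len(k)]^2 / total_var,
         total_variance = total_var,
         features = fm$features,
         scores = dplyr::bind_cols(fm$samples, scores),
         top_loadings = top),
    class = "projection_model"
  )
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("<projection_model> kind: %s, %d component(s)\n",
              x$kind, ncol(x$loadings)))
  if (x$kind == "pca") {
    cat("  explained variance fractions:",
        paste(sprintf("%.3f", x$explained_variance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Project new samples with a fitted model
#'
#' @param object a `projection_model`.
#' @param newdata a `feature_matrix` or numeric matrix with the same
#'   feature order as the training data.
#' @param ... unused.
#' @return Tibble of projected coordinates.
#' @export
predict.projection_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else newdata
  if (ncol(x) != length(object$mean)) abort("feature count mismatch")
  sc <- sweep(x, 2, object$mean) %*% object$loadings
  out <- as_tibble(sc, .name_repair = "minimal")
  names(out) <- colnames(object$scores)[
    (ncol(object$scores) - ncol(sc) + 1):ncol(object$scores)]
  out
}

#' Linear discriminant feature importance
#'
#' Standardizes every feature by its pooled within-group variance, fits a
#' linear discriminant model on the group labels, and reports per-feature
#' importance as the absolute discriminant coefficient (summed over
#' discriminants when there are more than two groups). Features with
#' (near-)zero pooled within-group variance fall back to the global
#' variance and are flagged.
#'
#' @param fm a `feature_matrix` whose `samples` carry a `group` column
#'   with >= 2 levels, each with >= 2 samples.
#' @return A `projection_model` (kind `"lda"`) whose `importance` element
#'   ranks features; `scores` holds the discriminant projections.
#' @export
lda_importance <- function(fm) {
  if (!"group" %in% names(fm$samples)) {
    abort("feature matrix has no `group` labels")
  }
  g <- fm$samples$group
  g <- factor(g)
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("each group needs at least 2 samples")
  x <- fm$x
  n <- nrow(x); k <- nlevels(g)

  within_var <- Reduce(`+`, lapply(levels(g), function(lv) {
    xs <- x[g == lv, , drop = FALSE]
    (nrow(xs) - 1) * apply(xs, 2, var)
  })) / (n - k)
  global_var <- apply(x, 2, var)
  fallback <- within_var < 1e-12
  scale_var <- ifelse(fallback, global_var, within_var)
  usable <- scale_var > 1e-12
  if (!any(usable)) abort("no feature has usable variance")
  xs <- sweep(x[, usable, drop = FALSE], 2, sqrt(scale_var[usable]), "/")

  fit <- suppressWarnings(MASS::lda(xs, grouping = g))
  coefs <- matrix(0, ncol(x), ncol(fit$scaling))
  coefs[usable, ] <- fit$scaling
  importance <- rowSums(abs(coefs))
  proj <- xs %*% fit$scaling
  scores <- as_tibble(proj, .name_repair = "minimal")
  names(scores) <- paste0("LD", seq_len(ncol(proj)))

  imp <- tibble(feature = fm$features, importance = importance,
                fallback_scaling = fallback)
  imp <- imp[order(-imp$importance), ]
  structure(
    list(kind = "lda", mean = colMeans(x), loadings = coefs,
         explained_variance = fit$svd^2 / sum(fit$svd^2),
         features = fm$features,
         scores = dplyr::bind_cols(fm$samples, scores),
         importance = imp,
         pooled_variance = within_var,
         flagged_features = fm$features[fallback]),
    class = "projection_model"
  )
}
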