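#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two conformations. Reflections are excluded: the returned rotation has
#' determinant +1 even for mirror-image targets.
#'
#' @param mobile,target `n x 3` coordinate matrices.
#' @param selection optional index vector: atoms used for the fit (the
#'   transform is applied to all atoms of `mobile`).
#' @return A list: `rotation` (3x3, acts on row vectors as
#'   `x %*% t(rotation)`), `translation`, `rmsd` (the minimized value over
#'   the selection), and `coords`, the transformed `mobile`.
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' fit <- kabsch_superpose(x, x)
#' fit$rmsd
#' @export
kabsch_superpose <- function(mobile, target, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  ms <- mobile[selection, , drop = FALSE]
  ts <- target[selection, , drop = FALSE]
  if (nrow(ms) != nrow(ts)) abort("selection counts differ between structures")
  if (nrow(ms) < 3) abort("need at least 3 atoms for superposition")
  cm <- colMeans(ms); ct <- colMeans(ts)
  msc <- sweep(ms, 2, cm); tsc <- sweep(ts, 2, ct)
  sv <- svd(crossprod(msc, tsc))            # H = mob' tgt
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-30)) {
    abort("selected atoms are (near-)collinear; rotation is ill-determined")
  }
  dsign <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  fitted_sel <- sweep(msc %*% t(r), 2, ct, "+")
  rmsd <- sqrt(mean(rowSums((fitted_sel - ts)^2)))
  coords <- sweep(sweep(mobile, 2, cm) %*% t(r), 2, ct, "+")
  list(rotation = r, translation = as.numeric(ct - r %*% cm),
       rmsd = rmsd, coords = coords)
}

## rmsd of two already-aligned coordinate sets
raw_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
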