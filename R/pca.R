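#' Fit a PCA transform with explained-variance targeting
#'
#' Mean-centres the spectra and computes principal components by singular
#' value decomposition. The number of retained components is the smallest `k`
#' whose cumulative explained variance reaches `variance_target` (default
#' 0.95), optionally capped at `max_components`. Component signs are fixed so
#' the largest-magnitude loading of each component is positive, making the
#' decomposition deterministic.
#'
#' @param spectra a [spectra_matrix()] (normally preprocessed).
#' @param variance_target fraction of variance to capture, in (0, 1].
#' @param max_components optional cap on the number of components.
#' @param fitted_on identifier of the training set, stored for audit.
#' @return an object of class `reduced_spectra` with fields `scores`
#'   (n x k), `loadings` (k x p, orthonormal rows), `center`,
#'   `explained_variance_ratio`, `n_components`, `grid`, `cell_ids`,
#'   `fitted_on`.
#' @export
pca_fit <- function(spectra, variance_target = 0.95, max_components = NULL,
                    fitted_on = "training") {
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (!is.numeric(variance_target) || variance_target <= 0 || variance_target > 1) {
    stop("'variance_target' must lie in (0, 1]")
  }
  x <- spectra$intensities
  n <- nrow(x)
  if (n < 2L) stop("PCA requires at least 2 spectra")
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  p <- ncol(x)
  if (n > p) {
    # tall matrices: eigendecomposition of the p x p covariance is several
    # times faster than a full SVD and equally deterministic
    eig <- eigen(crossprod(xc) / (n - 1), symmetric = TRUE)
    ev <- pmax(eig$values, 0)
    vt <- t(eig$vectors)
  } else {
    sv <- La.svd(xc, nu = 0L)
    ev <- sv$d^2 / (n - 1)
    vt <- sv$vt
  }
  total <- sum(ev)
  evr <- if (total > 0) ev / total else rep(0, length(ev))
  k_max <- max(1L, sum(ev > max(ev) * 1e-24))
  k <- which(cumsum(evr) >= variance_target - 1e-12)[1L]
  if (is.na(k)) k <- k_max
  k <- min(k, k_max)
  if (!is.null(max_components)) k <- min(k, as.integer(max_components))
  k <- max(k, 1L)
  loadings <- vt[seq_len(k), , drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[j, ]))
    if (loadings[j, i] < 0) loadings[j, ] <- -loadings[j, ]
  }
  scores <- xc %*% t(loadings)
  structure(list(
    scores = scores,
    loadings = loadings,
    center = center,
    explained_variance_ratio = evr[seq_len(k)],
    n_components = k,
    grid = spectra$grid,
    cell_ids = spectra$cell_ids,
    fitted_on = fitted_on
  ), class = "reduced_spectra")
}

#' @exportS3Method base::print
print.reduced_spectra <- function(x, ...) {
  cat(sprintf(
    "<reduced_spectra> %d cells, %d components (%.1f%% variance, fit on '%s')\n",
    nrow(x$scores), x$n_components,
    100 * sum(x$explained_variance_ratio), x$fitted_on
  ))
  invisible(x)
}

#' Project spectra onto a fitted PCA transform
#'
#' Computes `(x - center) %*% t(loadings)`. Applying the transform to its own
#' training data reproduces the stored scores; applying it to the training
#' mean spectrum gives the zero vector.
#'
#' @param transform a `reduced_spectra` from [pca_fit()].
#' @param spectra a [spectra_matrix()] on the same wavenumber grid.
#' @return numeric score matrix (n x k), rownames = cell ids.
#' @export
pca_transform <- function(transform, spectra) {
  stopifnot(inherits(transform, "reduced_spectra"),
    inherits(spectra, "spectra_matrix"))
  if (!grids_equal(transform$grid, spectra$grid)) {
    stop("wavenumber grid of the spectra does not match the PCA transform's grid")
  }
  scores <- sweep(spectra$intensities, 2L, transform$center) %*% t(transform$loadings)
  rownames(scores) <- spectra$cell_ids
  scores
}
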