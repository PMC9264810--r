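#' Principal component analysis by singular value decomposition
#'
#' Fits PCA on the centered data matrix via SVD (numerically preferable
#' to an explicit covariance eigendecomposition for wide spectral
#' matrices).  Component signs are fixed so that, for each loading, the
#' entry of largest magnitude is positive (first such entry on ties),
#' making fits fully deterministic.
#'
#' @param x numeric matrix, samples x wavenumbers.
#' @param n_components number of components to keep;
#'   `<= min(nrow(x) - 1, ncol(x))` and `<=` the numerical rank of the
#'   centered matrix.
#' @return an object of class `sers_pca` with fields `center`,
#'   `loadings` (orthonormal columns), `explained_variance_ratio`
#'   (fraction per kept component, non-increasing), `singular_values`,
#'   `n_components`.
#' @export
pca_fit <- function(x, n_components = 2) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop_sers("PCA needs >= 2 samples", class = "sersdisc_rank_error")
  if (n_components < 1 || n_components > min(n - 1, ncol(x)))
    stop_sers("n_components = %d not in 1..min(n-1, p) = %d",
              n_components, min(n - 1, ncol(x)),
              class = "sersdisc_rank_error")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc)
  tol <- max(dim(xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (n_components > rank)
    stop_sers("matrix rank %d is smaller than n_components = %d",
              rank, n_components, class = "sersdisc_rank_error")
  loadings <- sv$v[, seq_len(n_components), drop = FALSE]
  # deterministic sign convention
  for (k in seq_len(n_components)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) loadings[, k] <- -loadings[, k]
  }
  evr <- sv$d^2 / sum(sv$d^2)
  structure(list(center = center, loadings = loadings,
                 explained_variance_ratio = evr[seq_len(n_components)],
                 singular_values = sv$d, n_components = n_components),
            class = "sers_pca")
}

#' @export
print.sers_pca <- function(x, ...) {
  cat(sprintf("<sers_pca> %d components over %d variables; explained variance %s\n",
              x$n_components, length(x$center),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = " + ")))
  invisible(x)
}

#' Project data onto fitted principal components
#'
#' @param model a [pca_fit()] model.
#' @param x numeric matrix with the same number of columns the model was
#'   fitted on (a single sample may be passed as a vector).
#' @return scores matrix, samples x n_components.
#' @export
pca_project <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$center))
    stop_sers("data has %d columns; model expects %d", ncol(x),
              length(model$center), class = "sersdisc_dim_error")
  sweep(x, 2, model$center) %*% model$loadings
}
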