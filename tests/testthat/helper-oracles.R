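# Independent reference computations used to cross-check the package's
# own implementations.  These deliberately use different algorithms
# (eigendecompositions, Krylov least squares, pair enumeration) from the
# code under test.

# PLS1 regression vector via least squares on the Krylov basis
# {s, Gs, G^2 s, ...} of the normal equations (PLS is conjugate
# gradients on X'X b = X'y), independent of the NIPALS recursion.
oracle_pls1_coef <- function(x, y, n_components) {
  x0 <- sweep(x, 2, colMeans(x))
  y0 <- y - mean(y)
  s <- crossprod(x0, y0)
  g <- crossprod(x0)
  k <- matrix(0, ncol(x), n_components)
  v <- s
  for (a in seq_len(n_components)) {
    k[, a] <- v
    v <- g %*% v
  }
  drop(k %*% solve(t(k) %*% g %*% k, t(k) %*% s))
}

# AUROC by brute-force enumeration of all positive/negative pairs.
oracle_auroc <- function(pos, neg) {
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# Explained-variance ratios from an eigendecomposition of the sample
# covariance matrix (the package uses SVD of the centered matrix).
oracle_explained_variance <- function(x) {
  ev <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev / sum(ev)
}

# Angle in degrees between two directions (sign-invariant).
angle_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, ca)) * 180 / pi
}

# A dataset built directly from a matrix, for unit tests.
make_dataset <- function(mat, labels, grid = seq_len(ncol(mat)),
                         specimen = "plasma") {
  sers_dataset(grid, mat, labels, specimen)
}

# Small two-class Gaussian sample in d dimensions.
make_gaussians <- function(n_per_class, mu_pos, mu_neg, sigma_chol) {
  d <- length(mu_pos)
  z_pos <- matrix(rnorm(n_per_class * d), n_per_class) %*% sigma_chol
  z_neg <- matrix(rnorm(n_per_class * d), n_per_class) %*% sigma_chol
  list(scores = rbind(sweep(z_pos, 2, mu_pos, `+`),
                      sweep(z_neg, 2, mu_neg, `+`)),
       labels = rep(c("patient", "control"), each = n_per_class))
}
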