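#' Partial least squares discriminant analysis (NIPALS)
#'
#' PLS1 regression of a centered 0/1 class indicator (`control = 0`,
#' `patient = 1`) on the column-centered intensity matrix, fitted by
#' NIPALS with deflation of X (and y) after each component.  The
#' resulting model is both a projection (scores/loadings per component)
#' and a linear classifier through its regression vector.
#'
#' The +-1 coding sometimes seen for PLS-DA is an affine transform of
#' the 0/1 coding and yields identical class assignments.
#'
#' @param x numeric matrix, samples x wavenumbers.
#' @param labels `"control"`/`"patient"` per row; both classes required.
#' @param n_components number of latent components (default 2).
#' @param max_iter,tol NIPALS iteration cap and convergence tolerance on
#'   the score vector; non-convergence is an error.  With a single
#'   response the inner loop converges in one pass.
#' @return an object of class `sers_pls` with fields `center`, `y_mean`,
#'   `weights` (normalized X-weights `W`), `x_loadings` (`P`),
#'   `x_scores` (`T`), `y_loadings` (`q`, one per component),
#'   `coefficients` (regression vector `B = W (P'W)^-1 q`), and
#'   `n_components`.
#' @export
plsda_fit <- function(x, labels, n_components = 2,
                      max_iter = 500, tol = 1e-10) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  y <- as.numeric(labels == "patient")
  if (stats::var(y) == 0)
    stop_sers("PLS-DA needs both classes present",
              class = "sersdisc_class_error")
  center <- colMeans(x)
  y_mean <- mean(y)
  E <- sweep(x, 2, center)
  f <- y - y_mean
  n <- nrow(E); p <- ncol(E)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- f
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(E, u))
      nw <- sqrt(sum(w^2))
      if (nw == 0)
        stop_sers("X deflated to zero at component %d (rank exceeded)", a,
                  class = "sersdisc_rank_error")
      w <- w / nw
      t_vec <- drop(E %*% w)
      qa <- sum(f * t_vec) / sum(t_vec^2)
      u <- f * 1  # single response: u stays proportional to f
      if (sqrt(sum((t_vec - t_old)^2)) < tol * sqrt(sum(t_vec^2))) break
      t_old <- t_vec
      if (it == max_iter)
        stop_sers("NIPALS did not converge in %d iterations at component %d",
                  max_iter, a, class = "sersdisc_convergence_error")
    }
    p_vec <- drop(crossprod(E, t_vec)) / sum(t_vec^2)
    E <- E - tcrossprod(t_vec, p_vec)
    f <- f - qa * t_vec
    W[, a] <- w; P[, a] <- p_vec; Tm[, a] <- t_vec; q[a] <- qa
  }
  coef <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(center = center, y_mean = y_mean, weights = W,
                 x_loadings = P, x_scores = Tm, y_loadings = q,
                 coefficients = coef, n_components = n_components,
                 class_order = c("control", "patient")),
            class = "sers_pls")
}

#' @export
print.sers_pls <- function(x, ...) {
  cat(sprintf("<sers_pls> %d components over %d variables\n",
              x$n_components, length(x$center)))
  invisible(x)
}

#' Predict with a fitted PLS-DA model
#'
#' Computes the continuous indicator prediction
#' `yhat = y_mean + (x - center) B` and classifies as `"patient"` iff
#' `yhat > 0.5` (the midpoint of the 0/1 coding); ties go to
#' `"control"`.
#'
#' @param model a [plsda_fit()] model.
#' @param x matrix (or single-sample vector) of intensities.
#' @param type `"class"` (default) or `"response"` for the continuous
#'   prediction.
#' @return predicted labels, or numeric predictions for
#'   `type = "response"`.
#' @export
plsda_predict <- function(model, x, type = c("class", "response")) {
  type <- match.arg(type)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$center))
    stop_sers("data has %d columns; model expects %d", ncol(x),
              length(model$center), class = "sersdisc_dim_error")
  yhat <- model$y_mean + drop(sweep(x, 2, model$center) %*% model$coefficients)
  if (type == "response") return(yhat)
  ifelse(yhat > 0.5, "patient", "control")
}

#' Variable importance in projection (VIP) scores
#'
#' Wold's VIP: for variable j over components a,
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` with the
#' weights `w_a` unit-norm and `SSY_a = q_a^2 * t_a't_a` the y-variance
#' captured by component a.  The scores satisfy `sum(vip^2) = p`, so a
#' VIP above 1 marks a variable contributing more than average; 1.0 is
#' the conventional selection threshold.
#'
#' @param model a [plsda_fit()] model.
#' @param wavenumber optional wavenumber axis to attach (defaults to
#'   variable index).
#' @param threshold selection threshold stored with the profile
#'   (default 1.0).
#' @return an object of class `vip_profile`: data.frame-like list with
#'   `wavenumber`, `vip`, and `threshold`.
#' @export
vip_scores <- function(model, wavenumber = NULL, threshold = 1.0) {
  W <- model$weights
  p <- nrow(W)
  ssy <- model$y_loadings^2 * colSums(model$x_scores^2)
  w2 <- sweep(W^2, 2, colSums(W^2), `/`)  # guard: W columns are unit norm
  vip <- sqrt(p * drop(w2 %*% ssy) / sum(ssy))
  if (is.null(wavenumber)) wavenumber <- seq_len(p)
  structure(list(wavenumber = wavenumber, vip = vip, threshold = threshold),
            class = "vip_profile")
}

#' @export
print.vip_profile <- function(x, ...) {
  cat(sprintf("<vip_profile> %d variables, %d above threshold %.2f\n",
              length(x$vip), sum(x$vip > x$threshold), x$threshold))
  invisible(x)
}
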