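#' Linear soft-margin support vector machine
#'
#' Trains a two-class linear SVM (hinge loss, L2-regularized) by
#' deterministic dual coordinate descent.  The bias is handled through
#' an augmented constant feature, i.e. the solver minimizes
#' `0.5 * (||w||^2 + b^2) + cost * sum(hinge)`; with a regularized bias
#' the dual has simple box constraints and no equality constraint, and
#' every fit is exactly reproducible (fixed cyclic update order, no
#' randomization).
#'
#' @param scores numeric matrix, samples x d (typically PCA scores).
#' @param labels `"control"`/`"patient"` per row, both present;
#'   `"patient"` is coded +1.
#' @param cost soft-margin cost C (> 0), default 1.0.
#' @param max_sweeps cap on full passes over the data; exceeding it
#'   without meeting `tol` is a convergence error.
#' @param tol stop when the largest projected dual gradient over a
#'   sweep falls below `tol * max(1, mean squared sample norm)`; the
#'   scaling keeps the criterion attainable in floating point whatever
#'   the magnitude of the scores.
#' @return an object of class `sers_svm` with fields `w`, `b`, `alpha`,
#'   `cost`, `class_order = c("control", "patient")`.
#' @export
svm_fit_linear <- function(scores, labels, cost = 1.0,
                           max_sweeps = 1e6, tol = 1e-8) {
  x <- as.matrix(scores)
  labels <- as.character(labels)
  if (length(unique(labels)) != 2)
    stop_sers("SVM needs both classes present", class = "sersdisc_class_error")
  y <- ifelse(labels == "patient", 1, -1)
  xa <- cbind(x, 1)  # augmented bias feature
  tol_eff <- tol * max(1, mean(rowSums(xa^2)))
  fit <- svm_dcd(xa, y, cost, as.integer(max_sweeps), tol_eff)
  if (!fit$converged)
    stop_sers("SVM solver did not converge within %d sweeps", max_sweeps,
              class = "sersdisc_convergence_error")
  d <- ncol(x)
  structure(list(w = fit$wa[seq_len(d)], b = fit$wa[d + 1],
                 alpha = fit$alpha, cost = cost,
                 class_order = c("control", "patient")),
            class = "sers_svm")
}

#' Classify with a fitted linear SVM
#'
#' `"patient"` iff `w . x + b > 0`; a value of exactly zero goes to
#' `"control"`.
#'
#' @param model a [svm_fit_linear()] model.
#' @param scores matrix (or single-sample vector).
#' @return character vector of predicted labels.
#' @export
svm_predict_linear <- function(model, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  scores <- as.matrix(scores)
  if (ncol(scores) != length(model$w))
    stop_sers("scores have %d columns; model expects %d", ncol(scores),
              length(model$w), class = "sersdisc_dim_error")
  f <- drop(scores %*% model$w) + model$b
  ifelse(f > 0, "patient", "control")
}
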