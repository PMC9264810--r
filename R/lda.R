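#' Two-class Fisher linear discriminant
#'
#' Finds the direction maximizing the ratio of between-class to
#' within-class variance: `d = (S_w + reg * I)^-1 (mu_pos - mu_neg)`,
#' with `S_w` the pooled within-class scatter matrix.  The decision
#' threshold on the projected axis is placed where the two projected
#' class-conditional Gaussians (shared pooled variance, empirical
#' priors) have equal posterior probability.  Positive class is
#' `"patient"` throughout the package.
#'
#' @param scores numeric matrix, samples x d (typically PCA scores,
#'   d = 2).
#' @param labels `"control"`/`"patient"` per row; both classes must be
#'   present and at least 3 samples in total (a class may be a
#'   singleton inside a cross-validation fold; it then contributes no
#'   scatter).
#' @param regularization ridge added to `S_w`.  The default
#'   `1e-8 * trace(S_w) / d` is just enough to survive degenerate
#'   cross-validation folds; pass `0` to disable (singular `S_w` then
#'   errors).
#' @return an object of class `sers_lda` with fields `direction`,
#'   `threshold`, `class_order = c("control", "patient")`, `priors`, and
#'   the projected class means.
#' @export
lda_fit <- function(scores, labels, regularization = NULL) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  d <- ncol(scores)
  pos <- scores[labels == "patient", , drop = FALSE]
  neg <- scores[labels == "control", , drop = FALSE]
  if (nrow(pos) < 1 || nrow(neg) < 1 || nrow(pos) + nrow(neg) < 3)
    stop_sers("LDA needs both classes and >= 3 samples (got %d patient, %d control)",
              nrow(pos), nrow(neg), class = "sersdisc_class_error")
  mu_pos <- colMeans(pos)
  mu_neg <- colMeans(neg)
  sw <- crossprod(sweep(pos, 2, mu_pos)) + crossprod(sweep(neg, 2, mu_neg))
  if (is.null(regularization)) {
    # ridge scaled to the scatter; fall back to the mean-separation
    # scale when the classes carry no scatter at all, which turns the
    # rule into nearest-means
    scale <- max(sum(diag(sw)) / d, sum((mu_pos - mu_neg)^2))
    regularization <- 1e-8 * scale
  }
  direction <- tryCatch(
    solve(sw + diag(regularization, d), mu_pos - mu_neg),
    error = function(e)
      stop_sers("within-class scatter is singular; increase regularization",
                class = "sersdisc_singular_error"))
  n <- nrow(scores)
  priors <- c(control = nrow(neg) / n, patient = nrow(pos) / n)
  z <- drop(scores %*% direction)
  m_pos <- mean(z[labels == "patient"])
  m_neg <- mean(z[labels == "control"])
  s2 <- (sum((z[labels == "patient"] - m_pos)^2) +
         sum((z[labels == "control"] - m_neg)^2)) / (n - 2)
  threshold <- (m_pos + m_neg) / 2 +
    s2 * log(priors["control"] / priors["patient"]) / (m_pos - m_neg)
  structure(list(direction = direction, threshold = unname(threshold),
                 class_order = c("control", "patient"), priors = priors,
                 projected_means = c(control = m_neg, patient = m_pos),
                 pooled_variance = s2, regularization = regularization),
            class = "sers_lda")
}

#' Classify with a fitted linear discriminant
#'
#' Positive class (`"patient"`) iff the projected score exceeds the
#' threshold.  An exact tie goes to the class with the larger prior,
#' and to `"control"` at equal priors.
#'
#' @param model a [lda_fit()] model.
#' @param scores matrix (or single-row vector) in the model's space.
#' @return character vector of predicted labels.
#' @export
lda_predict <- function(model, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  scores <- as.matrix(scores)
  if (ncol(scores) != length(model$direction))
    stop_sers("scores have %d columns; model expects %d", ncol(scores),
              length(model$direction), class = "sersdisc_dim_error")
  z <- drop(scores %*% model$direction)
  out <- ifelse(z > model$threshold, "patient", "control")
  tie <- z == model$threshold
  if (any(tie)) {
    tie_class <- if (model$priors["patient"] > model$priors["control"])
      "patient" else "control"
    out[tie] <- tie_class
  }
  out
}
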