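#' Discrimination method specification
#'
#' Bundles a classifier chain name with its hyperparameters for use by
#' [loocv()] and [run_full_analysis()].
#'
#' @param method one of `"pca_lda"` (PCA projection + Fisher LDA),
#'   `"plsda"`, `"pca_svm"` (PCA + linear SVM), `"svm_raw"` (linear SVM
#'   on the full spectra), `"lda_raw"` (LDA on the full spectra).
#' @param n_components latent dimensions for the projection-based chains
#'   (default 2).
#' @param cost SVM soft-margin cost.
#' @param regularization LDA ridge (`NULL` = automatic, see [lda_fit()]).
#' @return list of class `method_spec`.
#' @export
method_spec <- function(method = c("pca_lda", "plsda", "pca_svm",
                                   "svm_raw", "lda_raw"),
                        n_components = 2, cost = 1.0,
                        regularization = NULL) {
  method <- match.arg(method)
  structure(list(method = method, n_components = n_components,
                 cost = cost, regularization = regularization),
            class = "method_spec")
}

# Fit the full model chain (projection + discriminant) on a training set.
fit_chain <- function(x, labels, spec, projection = NULL) {
  switch(spec$method,
    pca_lda = {
      proj <- projection %||% pca_fit(x, spec$n_components)
      disc <- lda_fit(pca_project(proj, x), labels, spec$regularization)
      list(projection = proj, discriminant = disc, spec = spec)
    },
    pca_svm = {
      proj <- projection %||% pca_fit(x, spec$n_components)
      disc <- svm_fit_linear(pca_project(proj, x), labels, cost = spec$cost)
      list(projection = proj, discriminant = disc, spec = spec)
    },
    plsda = {
      list(projection = NULL,
           discriminant = plsda_fit(x, labels, spec$n_components),
           spec = spec)
    },
    svm_raw = list(projection = NULL,
                   discriminant = svm_fit_linear(x, labels, cost = spec$cost),
                   spec = spec),
    lda_raw = list(projection = NULL,
                   discriminant = lda_fit(x, labels, spec$regularization),
                   spec = spec))
}

predict_chain <- function(chain, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  z <- if (!is.null(chain$projection)) pca_project(chain$projection, x) else x
  switch(chain$spec$method,
    pca_lda = , lda_raw = lda_predict(chain$discriminant, z),
    pca_svm = , svm_raw = svm_predict_linear(chain$discriminant, z),
    plsda = plsda_predict(chain$discriminant, z))
}

#' Confusion counts and derived metrics
#'
#' `confusion_counts()` tallies predictions against truth with
#' `"patient"` as the positive class.  `compute_metrics()` derives
#' accuracy, precision, sensitivity and specificity as percentages;
#' a metric whose denominator is zero is reported as `NA` (explicitly
#' not available), never as 0.
#'
#' @param truth,predicted character vectors of `"control"`/`"patient"`.
#' @return `confusion_counts()`: list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  list(tp = sum(truth == "patient" & predicted == "patient"),
       tn = sum(truth == "control" & predicted == "control"),
       fp = sum(truth == "control" & predicted == "patient"),
       fn = sum(truth == "patient" & predicted == "control"))
}

#' @rdname confusion_counts
#' @param confusion a `confusion_counts()` list (or anything with
#'   fields `tp`, `tn`, `fp`, `fn`).
#' @return `compute_metrics()`: list with `accuracy`, `precision`,
#'   `sensitivity`, `specificity` in percent (exact, unrounded; rounding
#'   happens only at presentation in [write_report()]).
#' @export
compute_metrics <- function(confusion) {
  cc <- confusion
  n <- cc$tp + cc$tn + cc$fp + cc$fn
  if (n == 0) stop_sers("empty confusion: n = 0",
                        class = "sersdisc_report_error")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(accuracy = ratio(cc$tp + cc$tn, n),
       precision = ratio(cc$tp, cc$tp + cc$fp),
       sensitivity = ratio(cc$tp, cc$tp + cc$fn),
       specificity = ratio(cc$tn, cc$tn + cc$fp))
}

#' Leave-one-out cross-validation of a discrimination chain
#'
#' For every sample, the entire model chain -- including the PCA or PLS
#' projection -- is refitted on the remaining n - 1 samples and applied
#' to the held-out sample, so no statistic of the held-out spectrum can
#' leak into its own prediction.  Setting `refit_projection = FALSE`
#' reproduces the laxer variant in which the projection is fitted once
#' on the full dataset and only the discriminant is refitted per fold
#' (sensitivity analysis only; the mode is stamped into the report).
#'
#' @param dataset a [sers_dataset()] with n >= 3 and >= 2 samples per
#'   class.
#' @param spec a [method_spec()].
#' @param refit_projection refit the projection inside every fold
#'   (default `TRUE`).
#' @return object of class `sers_evaluation`: list with
#'   `per_fold_predictions` (data.frame `sample_id`, `truth`,
#'   `predicted`), `confusion`, `metrics`, and `model_descriptor`.
#' @export
loocv <- function(dataset, spec, refit_projection = TRUE) {
  x <- dataset$matrix
  labels <- dataset$labels
  n <- nrow(x)
  if (n < 3) stop_sers("LOOCV needs n >= 3", class = "sersdisc_class_error")
  if (min(table(labels)) < 2)
    stop_sers("LOOCV needs >= 2 samples per class",
              class = "sersdisc_class_error")
  shared_proj <- NULL
  if (!refit_projection && spec$method %in% c("pca_lda", "pca_svm"))
    shared_proj <- pca_fit(x, spec$n_components)
  predicted <- character(n)
  for (i in seq_len(n)) {
    tr_labels <- labels[-i]
    if (length(unique(tr_labels)) < 2)
      stop_sers("fold holding out '%s' loses an entire class",
                dataset$sample_ids[i], class = "sersdisc_class_error")
    chain <- fit_chain(x[-i, , drop = FALSE], tr_labels, spec,
                       projection = shared_proj)
    predicted[i] <- predict_chain(chain, x[i, ])
  }
  cc <- confusion_counts(labels, predicted)
  structure(list(
    per_fold_predictions = data.frame(sample_id = dataset$sample_ids,
                                      truth = labels, predicted = predicted,
                                      stringsAsFactors = FALSE),
    confusion = cc,
    metrics = compute_metrics(cc),
    model_descriptor = list(method = spec$method,
                            n_components = spec$n_components,
                            cost = spec$cost,
                            regularization = spec$regularization,
                            refit_projection = refit_projection,
                            dataset = dataset$specimen,
                            band = attr(dataset, "band_name") %||% "full")),
    class = "sers_evaluation")
}

#' @export
print.sers_evaluation <- function(x, ...) {
  m <- x$metrics; cc <- x$confusion
  cat(sprintf("<sers_evaluation> %s (%s band): acc %s, prec %s, sens %s, spec %s [tp %d tn %d fp %d fn %d]\n",
              x$model_descriptor$method, x$model_descriptor$band,
              format_pct(m$accuracy), format_pct(m$precision),
              format_pct(m$sensitivity), format_pct(m$specificity),
              cc$tp, cc$tn, cc$fp, cc$fn))
  invisible(x)
}

#' Training vs cross-validated accuracy across model sizes
#'
#' For each candidate number of components, reports the mean training
#' accuracy of the per-fold models (each evaluated on its own training
#' set) alongside the LOOCV accuracy; their gap is the standard
#' overfitting diagnostic -- it widens as components are added beyond
#' what small cohorts support.
#'
#' @param dataset a [sers_dataset()].
#' @param spec a [method_spec()] whose `n_components` is swept.
#' @param component_grid integer vector of component counts.
#' @return data.frame with `n_components`, `train_accuracy`,
#'   `loocv_accuracy`, `gap` (percent points).
#' @export
train_test_gap <- function(dataset, spec, component_grid = c(2, 10)) {
  x <- dataset$matrix
  labels <- dataset$labels
  n <- nrow(x)
  rows <- lapply(component_grid, function(k) {
    sp <- spec
    sp$n_components <- k
    predicted <- character(n)
    train_acc <- numeric(n)
    for (i in seq_len(n)) {
      chain <- fit_chain(x[-i, , drop = FALSE], labels[-i], sp)
      predicted[i] <- predict_chain(chain, x[i, ])
      train_acc[i] <- mean(predict_chain(chain, x[-i, , drop = FALSE]) ==
                             labels[-i])
    }
    cv_acc <- 100 * mean(predicted == labels)
    tr_acc <- 100 * mean(train_acc)
    data.frame(n_components = k, train_accuracy = tr_acc,
               loocv_accuracy = cv_acc, gap = tr_acc - cv_acc)
  })
  do.call(rbind, rows)
}
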