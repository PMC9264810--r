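test_that("metrics reproduce the reference evaluation rows exactly", {
  # six reference PCA-LDA / PLS-DA confusion rows for 41-sample plasma
  # and 43-sample serum cohorts, with their expected percentages
  rows <- list(
    list(cc = list(tp = 26, tn = 10, fp = 4, fn = 1),
         m = c(87.8, 86.7, 96.3, 71.4)),
    list(cc = list(tp = 28, tn = 14, fp = 0, fn = 1),
         m = c(97.7, 100.0, 96.6, 100.0)),
    list(cc = list(tp = 23, tn = 10, fp = 4, fn = 4),
         m = c(80.5, 85.2, 85.2, 71.4)),
    list(cc = list(tp = 27, tn = 13, fp = 1, fn = 2),
         m = c(93.0, 96.4, 93.1, 92.9)),
    list(cc = list(tp = 26, tn = 11, fp = 3, fn = 1),
         m = c(90.2, 89.7, 96.3, 78.6)),
    list(cc = list(tp = 27, tn = 14, fp = 0, fn = 2),
         m = c(95.3, 100.0, 93.1, 100.0)))
  for (r in rows) {
    got <- compute_metrics(r$cc)
    rounded <- sersdisc:::round_half_up(
      c(got$accuracy, got$precision, got$sensitivity, got$specificity), 1)
    expect_equal(rounded, r$m)
  }
})

test_that("undefined ratios are reported as NA, never zero", {
  m <- compute_metrics(list(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 100)
  expect_equal(m$accuracy, 100)
  expect_error(compute_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               class = "sersdisc_report_error")
})

test_that("a 1-D nearest-mean toy problem is solved in every fold", {
  ds <- make_dataset(matrix(c(-1, -2, 1, 2), ncol = 1),
                     c("control", "control", "patient", "patient"))
  rep <- loocv(ds, method_spec("lda_raw"))
  expect_equal(rep$per_fold_predictions$predicted, ds$labels)
  expect_equal(rep$metrics$accuracy, 100)
  expect_equal(rep$confusion, list(tp = 2, tn = 2, fp = 0, fn = 0))
})

test_that("a separable synthetic cohort is classified perfectly", {
  sp <- preset_serum(seed = 1)  # strong planted effects, patient-only band
  ds <- snv_normalize(simulate_cohort(sp))
  rep <- loocv(ds, method_spec("pca_lda"))
  expect_equal(rep$metrics$accuracy, 100)
  expect_equal(with(rep$confusion, tp + tn + fp + fn), 43)
})

test_that("permuted labels collapse accuracy to the majority-class band", {
  ds <- snv_normalize(simulate_cohort(preset_plasma(seed = 1)))
  perm <- ds
  set.seed(1)
  perm$labels <- sample(ds$labels)
  acc <- loocv(perm, method_spec("pca_lda"))$metrics$accuracy / 100
  maj <- 27 / 41
  half <- 1.96 * sqrt(maj * (1 - maj) / 41)
  expect_gte(acc, maj - half)
  expect_lte(acc, maj + half)
})

test_that("no statistic of a held-out sample reaches its own fold model", {
  set.seed(61)
  sp <- preset_plasma(seed = 3)
  clean <- snv_normalize(simulate_cohort(sp))
  i <- 7
  corrupted <- clean
  corrupted$matrix[i, ] <- 1e4 * sin(seq_len(ncol(clean$matrix)))
  for (m in list(method_spec("pca_lda"), method_spec("plsda"))) {
    rep_corr <- loocv(corrupted, m)
    # fold i's model is fitted without row i, so it must coincide with a
    # chain fitted on the clean remainder
    chain_clean <- sersdisc:::fit_chain(clean$matrix[-i, ], clean$labels[-i], m)
    expect_equal(rep_corr$per_fold_predictions$predicted[i],
                 unname(sersdisc:::predict_chain(chain_clean,
                                                 corrupted$matrix[i, ])))
  }
})

test_that("LOOCV predictions are invariant to sample ordering", {
  ds <- snv_normalize(simulate_cohort(preset_plasma(seed = 2)))
  rep1 <- loocv(ds, method_spec("pca_lda"))
  set.seed(62)
  perm <- sample(nrow(ds$matrix))
  shuffled <- sers_dataset(ds$grid, ds$matrix[perm, ], ds$labels[perm],
                           ds$specimen, ds$sample_ids[perm])
  rep2 <- loocv(shuffled, method_spec("pca_lda"))
  ord <- match(rep1$per_fold_predictions$sample_id,
               rep2$per_fold_predictions$sample_id)
  expect_equal(rep2$per_fold_predictions$predicted[ord],
               rep1$per_fold_predictions$predicted)
})

test_that("folds that would lose a class are refused", {
  ds <- make_dataset(matrix(rnorm(4), ncol = 1),
                     c("control", "patient", "patient", "patient"))
  expect_error(loocv(ds, method_spec("lda_raw")),
               class = "sersdisc_class_error")
})

test_that("train/test gap sweeps components and respects rank limits", {
  # separable data: no gap at any feasible setting
  set.seed(63)
  g <- make_gaussians(6, c(8, 0, 0), c(-8, 0, 0), chol(diag(3) * 0.01))
  ds <- make_dataset(g$scores, g$labels)
  gaps <- train_test_gap(ds, method_spec("pca_lda"), c(1, 2))
  expect_equal(gaps$gap, c(0, 0))
  expect_equal(gaps$train_accuracy, c(100, 100))
  # settings above the feasible fold rank raise a rank error
  expect_error(train_test_gap(ds, method_spec("pca_lda"), 4),
               class = "sersdisc_rank_error")
})
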