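test_that("per-wavenumber t-tests reproduce hand-computed cases", {
  # identical groups: t = 0, p = 1
  m <- rbind(c(1, 5), c(3, 7), c(1, 5), c(3, 7))
  ds <- make_dataset(m, c("patient", "patient", "control", "control"))
  prof <- t_test_per_wavenumber(ds, "student")
  expect_equal(prof$t_stat, c(0, 0))
  expect_equal(prof$p_value, c(1, 1))

  # pooled-sd hand computation: patients 1..5, controls 2..6 -> t = -1
  m2 <- cbind(c(1:5, 2:6))
  ds2 <- make_dataset(m2, rep(c("patient", "control"), each = 5))
  prof2 <- t_test_per_wavenumber(ds2, "student")
  expect_equal(prof2$t_stat, -1.0, tolerance = 1e-12)
  expect_equal(prof2$mean_diff, -1.0)

  # near-complete separation drives p below any fixed alpha
  m3 <- cbind(c(0, 1e-9, -1e-9, 2e-9, 1, 1 + 1e-9, 1 - 1e-9, 1 + 2e-9))
  ds3 <- make_dataset(m3, rep(c("control", "patient"), each = 4))
  expect_lt(t_test_per_wavenumber(ds3)$p_value, 1e-6)
})

test_that("t-test p-values agree with the reference implementation", {
  set.seed(51)
  for (variant in c("welch", "student")) {
    m <- matrix(rnorm(12 * 30), 12)
    labels <- rep(c("patient", "control"), c(7, 5))
    ds <- make_dataset(m, labels)
    prof <- t_test_per_wavenumber(ds, variant)
    ref <- vapply(seq_len(ncol(m)), function(j) {
      t.test(m[labels == "patient", j], m[labels == "control", j],
             var.equal = (variant == "student"))$p.value
    }, 0)
    expect_equal(prof$p_value, ref, tolerance = 1e-10)
  }
})

test_that("zero-variance columns are flagged, not tested", {
  m <- cbind(c(1, 2, 2, 3), c(5, 5, 5, 5))
  ds <- make_dataset(m, c("patient", "patient", "control", "control"))
  prof <- t_test_per_wavenumber(ds)
  expect_equal(prof$p_value[2], 1)
  expect_equal(attr(prof, "degenerate"), 2L)
})

test_that("BH step-up matches hand enumeration and is monotone in fdr", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(bh_correct(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_true(bh_correct(0.04, 0.05))  # m = 1 reduces to p <= fdr
  expect_false(bh_correct(0.06, 0.05))
  expect_error(bh_correct(c(0.5, 1.2)), class = "sersdisc_input_error")

  set.seed(52)
  for (rep in 1:20) {
    p <- runif(50)^2
    lo <- bh_correct(p, 0.01)
    hi <- bh_correct(p, 0.10)
    expect_true(all(hi[lo]))  # rejections at 1% are kept at 10%
  }
})

test_that("AUROC follows the Mann-Whitney identity with ties at 1/2", {
  m <- cbind(c(3, 5, 1, 4), c(10, 20, 1, 2), c(7, 7, 7, 7))
  ds <- make_dataset(m, c("patient", "patient", "control", "control"))
  auc <- auroc_per_wavenumber(ds)
  expect_equal(auc, c(0.75, 1.0, 0.5))  # brute-force pair counts

  set.seed(53)
  m2 <- matrix(rnorm(14 * 10), 14)
  labels <- rep(c("patient", "control"), 7)
  ds2 <- make_dataset(m2, labels)
  auc2 <- auroc_per_wavenumber(ds2)
  brute <- vapply(seq_len(ncol(m2)), function(j)
    oracle_auroc(m2[labels == "patient", j], m2[labels == "control", j]), 0)
  expect_equal(auc2, brute, tolerance = 1e-12)

  # antisymmetry under sign flip
  neg <- ds2; neg$matrix <- -neg$matrix
  expect_equal(auroc_per_wavenumber(neg) + auc2, rep(1, 10),
               tolerance = 1e-12)
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(54)
  m <- matrix(rnorm(20 * 5) + rep(c(0.8, 0), c(12, 8)), 20)
  labels <- rep(c("patient", "control"), c(12, 8))
  ds <- make_dataset(m, labels)
  auc <- auroc_per_wavenumber(ds)
  ref <- vapply(seq_len(5), function(j)
    as.numeric(pROC::auc(pROC::roc(labels, m[, j], levels = c("control", "patient"),
                                   direction = "<", quiet = TRUE))), 0)
  expect_equal(auc, ref, tolerance = 1e-12)
})

test_that("significant runs are maximal and short runs are discarded", {
  grid <- 100:130
  expect_equal(nrow(significant_bands(rep(FALSE, 31), grid)), 0)
  all_true <- significant_bands(rep(TRUE, 31), grid)
  expect_equal(c(all_true$low, all_true$high), c(100, 130))

  mask <- rep(FALSE, 31)
  mask[10:14] <- TRUE  # run of 5
  mask[20:21] <- TRUE  # run of 2, below min_run_length
  runs <- significant_bands(mask, grid, min_run_length = 3)
  expect_equal(nrow(runs), 1)
  expect_equal(c(runs$low, runs$high), c(grid[10], grid[14]))
})

test_that("mean-spectrum summaries detect peaks and annotate bands", {
  # two flat classes: nothing to detect
  flat <- make_dataset(rbind(rep(1, 50), rep(2, 50)),
                       c("control", "patient"), grid = 951:1000)
  sumf <- mean_spectra_with_annotations(flat)
  expect_equal(nrow(sumf$peaks), 0)

  # a single Lorentzian at 1010 1/cm is found within +-2 1/cm
  sp <- cohort_spec(n_control = 5, n_patient = 5,
                    peaks = list(peak_spec(1010, 1, 1)),
                    grid = grid_spec(900, 1100, 1),
                    baseline_amp = 0, scatter_sd = 0, noise_sd = 0.005,
                    jitter_sd = 0, amplitude_cv = 0.05, seed = 5)
  ds <- simulate_cohort(sp)
  peaks <- mean_spectra_with_annotations(ds)$peaks
  grouped <- peaks[peaks$curve == "grouped", ]
  expect_equal(nrow(grouped), 1)
  expect_lte(abs(grouped$wavenumber - 1010), 2)
  # class-wise and grouped curves are all reported
  expect_setequal(unique(peaks$curve), c("control", "patient", "grouped"))
})

test_that("the combined univariate profile carries BH mask and AUROC", {
  set.seed(55)
  m <- matrix(rnorm(20 * 30), 20)
  m[11:20, 5] <- m[11:20, 5] + 4
  ds <- make_dataset(m, rep(c("control", "patient"), each = 10))
  prof <- univariate_profile(ds)
  expect_true(prof$bh_significant[5])
  expect_gt(prof$auroc[5], 0.9)
  expect_true(all(prof$p_value[prof$bh_significant] <= 0.05))
})
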