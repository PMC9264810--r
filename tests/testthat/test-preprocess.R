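test_that("grid and band specs validate their invariants", {
  expect_length(grid_nodes(grid_spec(350, 2200, 1)), 1851)
  expect_error(grid_spec(100, 100), class = "sersdisc_grid_error")
  expect_error(grid_spec(0, 10, 3), class = "sersdisc_grid_error")
  expect_error(band_spec(list(c(5, 1))), class = "sersdisc_band_error")
  expect_error(band_spec(list(c(1, 5), c(4, 8))),
               class = "sersdisc_band_error")
})

test_that("resampling interpolates linearly and is exact on affine spectra", {
  s <- sers_spectrum("s", "plasma", "control", c(100, 102), c(0, 2))
  out <- resample_to_grid(s, grid_spec(100, 102, 1))
  expect_equal(out$intensities, c(0, 1, 2))

  # identity when the native grid already matches
  s2 <- sers_spectrum("s", "plasma", "control", 350:360, rnorm(11))
  expect_equal(resample_to_grid(s2, grid_spec(350, 360, 1))$intensities,
               s2$intensities)

  # affine intensity in wavenumber survives any in-range resampling
  wn <- sort(runif(40, 300, 2400))
  aff <- sers_spectrum("a", "serum", "patient", wn, 3 - 0.25 * wn)
  res <- resample_to_grid(aff, grid_spec(350, 2200, 1))
  expect_equal(res$intensities, 3 - 0.25 * res$wavenumbers,
               tolerance = 1e-12)
  expect_length(res$intensities, 1851)

  expect_error(resample_to_grid(s, grid_spec(90, 102, 1)),
               class = "sersdisc_grid_error")
})

test_that("SNV normalizes rows to zero mean and unit sd and is idempotent", {
  ds <- make_dataset(rbind(c(1, 2, 3), c(4, 4, 7)),
                     c("control", "patient"))
  out <- snv_normalize(ds)
  expect_equal(out$matrix[1, ], c(-1, 0, 1))  # sample sd (n-1) is 1
  expect_equal(rowMeans(out$matrix), c(0, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(apply(out$matrix, 1, sd), c(1, 1), tolerance = 1e-10,
               ignore_attr = TRUE)

  twice <- snv_normalize(out)
  expect_equal(twice$matrix, out$matrix, tolerance = 1e-10)

  const <- make_dataset(rbind(c(5, 5, 5), c(1, 2, 3)),
                        c("control", "patient"))
  expect_error(snv_normalize(const), "s1",
               class = "sersdisc_degenerate_error")
})

test_that("area normalization scales rows to unit trapezoidal integral", {
  ds <- make_dataset(matrix(1, 2, 11), c("control", "patient"),
                     grid = 0:10)
  out <- area_normalize(ds, band_spec(list(c(0, 10))))
  expect_equal(out$matrix, matrix(0.1, 2, 11), ignore_attr = TRUE)

  two <- make_dataset(rbind(c(0, 2), c(1, 3)), c("control", "patient"),
                      grid = 0:1)
  norm1 <- area_normalize(two, band_spec(list(c(0, 1))))
  expect_equal(norm1$matrix[1, ], c(0, 2))  # trapezoid area was 1.0
  norm2 <- area_normalize(norm1, band_spec(list(c(0, 1))))
  expect_equal(norm2$matrix, norm1$matrix, tolerance = 1e-9)

  neg <- make_dataset(rbind(c(-1, -1), c(1, 1)), c("control", "patient"),
                      grid = 0:1)
  expect_error(area_normalize(neg, band_spec(list(c(0, 1)))),
               class = "sersdisc_degenerate_error")
})

test_that("band restriction keeps inclusive endpoints and counts add up", {
  mat <- matrix(rnorm(2 * 1851), 2)
  ds <- make_dataset(mat, c("control", "patient"), grid = 350:2200)
  expect_equal(ncol(restrict_band(ds, band_spec(list(c(1200, 1700))))$matrix),
               501)
  both <- restrict_band(ds, band_spec(list(c(825, 1050), c(1506, 1750))))
  expect_equal(ncol(both$matrix), 226 + 245)
  a <- restrict_band(ds, band_spec(list(c(825, 1050))))
  b <- restrict_band(ds, band_spec(list(c(1506, 1750))))
  expect_equal(ncol(both$matrix), ncol(a$matrix) + ncol(b$matrix))
  whole <- restrict_band(ds, band_spec(list(c(350, 2200))))
  expect_equal(whole$matrix, ds$matrix, ignore_attr = TRUE)
  expect_error(restrict_band(ds, band_spec(list(c(2300, 2400)))),
               class = "sersdisc_band_error")
})

test_that("ALS baseline removal preserves peaks while removing drift", {
  wn <- 350:1350
  flat <- sers_spectrum("f", "plasma", "control", wn, rep(0, length(wn)))
  expect_equal(baseline_correct(flat)$intensities, rep(0, length(wn)))

  # an additive constant lies in the second-difference null space
  const <- sers_spectrum("c", "plasma", "control", wn, rep(3, length(wn)))
  expect_lt(max(abs(baseline_correct(const)$intensities)), 1e-6)

  # Lorentzian on a linear ramp with a stiff penalty: ramp removed,
  # peak height kept
  peak <- 0.8 * 8^2 / ((wn - 850)^2 + 8^2)
  ramp <- 0.001 * (wn - 350)
  spec <- sers_spectrum("p", "plasma", "control", wn, peak + ramp)
  corr <- baseline_correct(spec, lam = 1e7)
  apex <- which.max(corr$intensities)
  expect_equal(wn[apex], 850, tolerance = 2)
  expect_equal(max(corr$intensities), 0.8, tolerance = 0.05 * 0.8)
  # away from the peak the residual is near zero despite the ramp
  expect_lt(max(abs(corr$intensities[wn < 600])), 0.05)
})

test_that("preprocessing steps are recorded as a provenance chain", {
  ds <- make_dataset(matrix(rnorm(20), 2), c("control", "patient"),
                     grid = seq(100, 145, 5))
  out <- restrict_band(snv_normalize(ds), band_spec(list(c(100, 120))))
  steps <- vapply(out$provenance, `[[`, "", "step")
  expect_equal(steps, c("snv_normalize", "restrict_band"))
})
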