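#' Wavenumber grid and band specifications
#'
#' `grid_spec()` describes the equally spaced wavenumber axis spectra are
#' aligned to (default step 1 cm^-1, the sampling used throughout the
#' pipeline).  `band_spec()` describes a union of closed wavenumber
#' intervals used to restrict analyses to a spectral window.
#'
#' @param start,stop grid limits in cm^-1, `start < stop`.
#' @param step grid spacing in cm^-1 (> 0); `(stop - start)` must be an
#'   integer multiple of `step` (tolerance 1e-9).
#' @return `grid_spec()`: an object of class `grid_spec`;
#'   `grid_nodes()` its numeric node vector.
#' @examples
#' g <- grid_spec(350, 2200)
#' length(grid_nodes(g))  # 1851
#' @export
grid_spec <- function(start = 350, stop = 2200, step = 1) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (!(start < stop)) stop_sers("grid start must be < stop",
                                 class = "sersdisc_grid_error")
  if (step <= 0) stop_sers("grid step must be > 0",
                           class = "sersdisc_grid_error")
  k <- (stop - start) / step
  if (abs(k - round(k)) > 1e-9)
    stop_sers("(stop - start) = %g is not a multiple of step = %g",
              stop - start, step, class = "sersdisc_grid_error")
  structure(list(start = start, stop = stop, step = step),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param grid a `grid_spec`.
#' @export
grid_nodes <- function(grid) {
  grid$start + grid$step * (0:round((grid$stop - grid$start) / grid$step))
}

#' @rdname grid_spec
#' @param intervals list of `c(low, high)` pairs (cm^-1), `low < high`,
#'   non-overlapping; they are stored sorted by `low`.
#' @return `band_spec()`: an object of class `band_spec`.
#' @export
band_spec <- function(intervals) {
  if (is.numeric(intervals) && length(intervals) == 2)
    intervals <- list(intervals)
  ivs <- lapply(intervals, function(p) {
    if (length(p) != 2 || !(p[1] < p[2]))
      stop_sers("band interval must be c(low, high) with low < high",
                class = "sersdisc_band_error")
    as.numeric(p)
  })
  ivs <- ivs[order(vapply(ivs, `[`, 0, 1))]
  lows <- vapply(ivs, `[`, 0, 1)
  highs <- vapply(ivs, `[`, 0, 2)
  if (length(ivs) > 1 && any(lows[-1] <= highs[-length(highs)]))
    stop_sers("band intervals overlap", class = "sersdisc_band_error")
  structure(list(intervals = ivs), class = "band_spec")
}

# Logical mask over grid values: inside some closed interval.
band_mask <- function(band, grid_values) {
  m <- rep(FALSE, length(grid_values))
  for (iv in band$intervals)
    m <- m | (grid_values >= iv[1] - 1e-9 & grid_values <= iv[2] + 1e-9)
  m
}

#' Resample a spectrum onto an equally spaced grid
#'
#' Linear interpolation at every node of `grid`; the grid must be fully
#' contained in the spectrum's native wavenumber range.
#'
#' @param spectrum a [sers_spectrum()].
#' @param grid a [grid_spec()].
#' @return a [sers_spectrum()] on the new grid.
#' @export
resample_to_grid <- function(spectrum, grid) {
  nodes <- grid_nodes(grid)
  rng <- range(spectrum$wavenumbers)
  if (nodes[1] < rng[1] - 1e-9 || nodes[length(nodes)] > rng[2] + 1e-9)
    stop_sers(
      "grid %g-%g extends beyond native range %g-%g of '%s'",
      nodes[1], nodes[length(nodes)], rng[1], rng[2], spectrum$sample_id,
      class = "sersdisc_grid_error")
  y <- stats::approx(spectrum$wavenumbers, spectrum$intensities,
                     xout = nodes, method = "linear", rule = 1)$y
  sers_spectrum(spectrum$sample_id, spectrum$specimen, spectrum$label,
                nodes, y)
}

#' Standard normal variate normalization
#'
#' Scales and offsets each spectrum (row) to zero mean and unit standard
#' deviation, removing per-spectrum multiplicative scatter and additive
#' offset.  The sample standard deviation (denominator n-1) is the
#' default; `denominator = "n"` uses the population form -- the two only
#' differ by a common scale factor per spectrum.
#'
#' @param dataset a [sers_dataset()].
#' @param denominator `"n-1"` (sample sd, default) or `"n"`.
#' @return the normalized dataset; each row has mean 0 and sd 1.
#' @export
snv_normalize <- function(dataset, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  x <- dataset$matrix
  mu <- rowMeans(x)
  centered <- x - mu
  ss <- rowSums(centered^2)
  n <- ncol(x)
  sd <- sqrt(ss / (if (denominator == "n-1") n - 1 else n))
  if (any(sd == 0)) {
    bad <- dataset$sample_ids[which(sd == 0)[1]]
    stop_sers("degenerate spectrum '%s': constant intensities (sd = 0)",
              bad, class = "sersdisc_degenerate_error")
  }
  dataset$matrix <- centered / sd
  dimnames(dataset$matrix) <- list(dataset$sample_ids, NULL)
  record_step(dataset, "snv_normalize", list(denominator = denominator))
}

#' Area normalization
#'
#' Divides each spectrum by its trapezoidal integral over `band`, so the
#' integrated area under the curve in that window is 1.  Used for
#' figure-style mean spectra; the multivariate chain uses
#' [snv_normalize()].
#'
#' @param dataset a [sers_dataset()].
#' @param band a [band_spec()] (default: the dataset's full grid range).
#' @return the normalized dataset.
#' @export
area_normalize <- function(dataset, band = NULL) {
  if (is.null(band)) band <- band_spec(list(range(dataset$grid)))
  keep <- band_mask(band, dataset$grid)
  if (!any(keep)) stop_sers("band selects no grid nodes",
                            class = "sersdisc_band_error")
  w <- dataset$grid[keep]
  areas <- apply(dataset$matrix[, keep, drop = FALSE], 1,
                 function(y) trapz_integral(w, y))
  if (any(areas <= 0)) {
    bad <- dataset$sample_ids[which(areas <= 0)[1]]
    stop_sers("degenerate spectrum '%s': non-positive area %g over band",
              bad, areas[areas <= 0][1], class = "sersdisc_degenerate_error")
  }
  dataset$matrix <- dataset$matrix / areas
  dimnames(dataset$matrix) <- list(dataset$sample_ids, NULL)
  record_step(dataset, "area_normalize",
              list(band = lapply(band$intervals, identity)))
}

#' Asymmetric-least-squares baseline correction
#'
#' Estimates a smooth fluorescence-like background by iteratively
#' reweighted penalized least squares: the baseline z minimizes
#' `sum(w * (y - z)^2) + lam * sum(diff(z, differences = 2)^2)`, with
#' weights `p_asym` where `y > z` and `1 - p_asym` elsewhere, so the
#' baseline hugs the lower envelope of the spectrum.  Returns the
#' spectrum minus the estimated baseline.
#'
#' @param spectrum a [sers_spectrum()].
#' @param lam smoothness penalty (> 0); larger values give stiffer
#'   baselines.  Default 1e5.
#' @param p_asym asymmetry weight in (0, 1); default 0.01.
#' @param iters number of reweighting iterations (>= 1); default 10.
#' @return corrected [sers_spectrum()]; the estimated baseline is
#'   attached as attribute `"baseline"`.
#' @export
baseline_correct <- function(spectrum, lam = 1e5, p_asym = 0.01,
                             iters = 10) {
  stopifnot(lam > 0, p_asym > 0, p_asym < 1, iters >= 1)
  y <- spectrum$intensities
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- lam * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(iters)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    w <- ifelse(y > z, p_asym, 1 - p_asym)
  }
  out <- sers_spectrum(spectrum$sample_id, spectrum$specimen,
                       spectrum$label, spectrum$wavenumbers, y - z)
  attr(out, "baseline") <- z
  out
}

#' Restrict a dataset to a spectral band
#'
#' Keeps exactly the grid columns whose wavenumber lies inside some
#' interval of `band` (closed endpoints).
#'
#' @param dataset a [sers_dataset()].
#' @param band a [band_spec()].
#' @return the restricted dataset.
#' @export
restrict_band <- function(dataset, band) {
  keep <- band_mask(band, dataset$grid)
  if (!any(keep))
    stop_sers("band selects no grid nodes in %g-%g cm^-1",
              min(dataset$grid), max(dataset$grid),
              class = "sersdisc_band_error")
  dataset$grid <- dataset$grid[keep]
  dataset$matrix <- dataset$matrix[, keep, drop = FALSE]
  record_step(dataset, "restrict_band",
              list(band = lapply(band$intervals, identity)))
}
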