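#' Per-wavenumber two-sample t-tests
#'
#' Tests, at every grid node independently, whether mean intensity
#' differs between patients and controls.  Welch's unequal-variance
#' test is the default (the cohorts are unbalanced); the pooled-variance
#' Student test is available as a variant.  The statistic is oriented as
#' patient minus control, matching the `mean_diff` column.
#'
#' Columns where both groups have zero variance cannot be tested: their
#' p-value is set to 1 and the column index is recorded in the
#' `degenerate` attribute.
#'
#' @param dataset a [sers_dataset()] with >= 2 samples per class.
#' @param variant `"welch"` (default) or `"student"`.
#' @return data.frame of class `univariate_profile` with columns
#'   `wavenumber`, `t_stat`, `p_value`, `mean_diff`, `mean_control`,
#'   `mean_patient`.
#' @export
t_test_per_wavenumber <- function(dataset, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  pat <- dataset$matrix[dataset$labels == "patient", , drop = FALSE]
  ctl <- dataset$matrix[dataset$labels == "control", , drop = FALSE]
  n1 <- nrow(pat); n0 <- nrow(ctl)
  if (n1 < 2 || n0 < 2)
    stop_sers("t-tests need >= 2 samples per class (got %d patient, %d control)",
              n1, n0, class = "sersdisc_class_error")
  m1 <- colMeans(pat); m0 <- colMeans(ctl)
  v1 <- colSums(sweep(pat, 2, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(ctl, 2, m0)^2) / (n0 - 1)
  if (variant == "welch") {
    se2 <- v1 / n1 + v0 / n0
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n0)
    df <- rep(n1 + n0 - 2, length(se2))
  }
  degenerate <- which(se2 == 0)
  se2[degenerate] <- NA_real_
  t_stat <- (m1 - m0) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  t_stat[degenerate] <- 0
  p[degenerate] <- 1
  out <- data.frame(wavenumber = dataset$grid, t_stat = t_stat,
                    p_value = p, mean_diff = m1 - m0,
                    mean_control = m0, mean_patient = m1)
  attr(out, "variant") <- variant
  attr(out, "degenerate") <- degenerate
  class(out) <- c("univariate_profile", "data.frame")
  out
}

#' Benjamini-Hochberg rejection mask
#'
#' Standard step-up FDR control: with sorted p-values, the largest k
#' with `p_(k) <= k * fdr / m` determines the rejection set.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param fdr target false discovery rate in (0, 1); default 0.05.
#' @return logical vector, `TRUE` where the hypothesis is rejected.
#' @export
bh_correct <- function(p_values, fdr = 0.05) {
  stopifnot(fdr > 0, fdr < 1)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop_sers("p-values must lie in [0, 1]", class = "sersdisc_input_error")
  stats::p.adjust(p_values, method = "BH") <= fdr
}

#' Per-wavenumber AUROC
#'
#' Area under the ROC curve for each grid node separately, computed via
#' the Mann-Whitney rank identity with midrank tie handling (tied
#' patient/control pairs contribute 1/2).  Positive class is
#' `"patient"`: an AUROC above 0.5 means patients tend to have higher
#' intensity.
#'
#' @param dataset a [sers_dataset()] with both classes present.
#' @param positive positive class, default `"patient"`.
#' @return numeric vector of AUROC values in `[0, 1]`, one per column.
#' @export
auroc_per_wavenumber <- function(dataset, positive = "patient") {
  is_pos <- dataset$labels == positive
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0)
    stop_sers("AUROC needs both classes present",
              class = "sersdisc_class_error")
  apply(dataset$matrix, 2, function(col) {
    r <- rank(col)  # midranks handle ties
    (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
}

#' Maximal runs of significant grid nodes
#'
#' Collapses a per-node significance mask into maximal contiguous runs,
#' discarding runs shorter than `min_run_length` nodes (single-node
#' artifacts are rarely interpretable on a 1 cm^-1 grid).
#'
#' @param mask logical vector over the grid.
#' @param grid wavenumber vector, same length as `mask`.
#' @param min_run_length minimum run length in grid nodes (default 3).
#' @return object of class `band_run_set`: data.frame with columns
#'   `low`, `high` (first/last wavenumber of each kept run) and
#'   `n_nodes`.
#' @export
significant_bands <- function(mask, grid, min_run_length = 3) {
  stopifnot(length(mask) == length(grid))
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run_length
  out <- data.frame(low = grid[starts[keep]], high = grid[ends[keep]],
                    n_nodes = r$lengths[keep])
  attr(out, "min_run_length") <- min_run_length
  class(out) <- c("band_run_set", "data.frame")
  out
}

# Local maxima with a simple topographic prominence rule: walk outward
# from each candidate until terrain higher than the peak (or an edge) is
# met; prominence = peak height minus the higher of the two side minima.
find_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  keep <- vapply(cand, function(i) {
    left <- if (i > 1) min_side(y, i, -1L) else y[i]
    right <- if (i < n) min_side(y, i, 1L) else y[i]
    (y[i] - max(left, right)) >= min_prominence
  }, TRUE)
  cand[keep]
}

min_side <- function(y, i, step) {
  lo <- y[i]
  j <- i + step
  while (j >= 1 && j <= length(y) && y[j] <= y[i]) {
    lo <- min(lo, y[j])
    j <- j + step
  }
  lo
}

#' Annotated mean-spectrum summary
#'
#' Produces the figure-style summary used to present a cohort: class-wise
#' and grouped mean spectra with detected peaks, plus shading for
#' BH-significant wavenumber runs and VIP > threshold runs.  Peaks are
#' local maxima with topographic prominence at least
#' `peak_prominence_frac` of the spectrum's intensity range; class-wise
#' and grouped peak lists can legitimately differ when class means do not
#' align, so both are reported.
#'
#' @param dataset a [sers_dataset()].
#' @param profile a [t_test_per_wavenumber()] profile with a
#'   `bh_significant` column, or `NULL`.
#' @param vip a [vip_scores()] profile on the same grid, or `NULL`.
#' @param peak_prominence_frac prominence threshold as a fraction of
#'   (max - min) of each mean spectrum; default 0.02.
#' @return list of class `sers_mean_summary` with `table` (tidy
#'   per-wavenumber data.frame), `peaks` (per-curve peak table), and
#'   `plot` (a ggplot object).
#' @export
mean_spectra_with_annotations <- function(dataset, profile = NULL, vip = NULL,
                                          peak_prominence_frac = 0.02) {
  grid <- dataset$grid
  mean_ctl <- colMeans(dataset$matrix[dataset$labels == "control", ,
                                      drop = FALSE])
  mean_pat <- colMeans(dataset$matrix[dataset$labels == "patient", ,
                                      drop = FALSE])
  mean_all <- colMeans(dataset$matrix)
  curves <- list(control = mean_ctl, patient = mean_pat, grouped = mean_all)
  peaks <- do.call(rbind, lapply(names(curves), function(nm) {
    y <- curves[[nm]]
    idx <- find_peaks(y, min_prominence = peak_prominence_frac *
                           (max(y) - min(y)))
    if (!length(idx)) return(NULL)
    data.frame(curve = nm, wavenumber = grid[idx], intensity = y[idx])
  }))
  if (is.null(peaks))
    peaks <- data.frame(curve = character(), wavenumber = numeric(),
                        intensity = numeric())
  tab <- data.frame(wavenumber = grid, mean_control = mean_ctl,
                    mean_patient = mean_pat, mean_grouped = mean_all)
  tab$bh_significant <- if (!is.null(profile) &&
                            !is.null(profile$bh_significant))
    profile$bh_significant else NA
  tab$vip <- if (!is.null(vip)) vip$vip else NA_real_
  tab$vip_gt_threshold <- if (!is.null(vip)) vip$vip > vip$threshold else NA
  plot <- mean_summary_plot(tab, peaks)
  structure(list(table = tab, peaks = peaks, plot = plot),
            class = "sers_mean_summary")
}

mean_summary_plot <- function(tab, peaks) {
  long <- rbind(
    data.frame(wavenumber = tab$wavenumber, intensity = tab$mean_control,
               curve = "control"),
    data.frame(wavenumber = tab$wavenumber, intensity = tab$mean_patient,
               curve = "patient"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$wavenumber,
                                          y = .data$intensity,
                                          colour = .data$curve))
  shade <- function(mask, fill) {
    if (all(is.na(mask)) || !any(mask, na.rm = TRUE)) return(NULL)
    runs <- significant_bands(!is.na(mask) & mask, tab$wavenumber,
                              min_run_length = 1)
    ggplot2::annotate("rect", xmin = runs$low - 0.5, xmax = runs$high + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = fill)
  }
  p <- p + shade(tab$bh_significant, "orange") +
    shade(tab$vip_gt_threshold, "steelblue") +
    ggplot2::geom_line(linewidth = 0.3)
  cls_peaks <- peaks[peaks$curve != "grouped", , drop = FALSE]
  if (nrow(cls_peaks))
    p <- p + ggplot2::geom_point(data = cls_peaks,
                                 ggplot2::aes(x = .data$wavenumber,
                                              y = .data$intensity,
                                              colour = .data$curve),
                                 shape = 4, size = 1.4)
  p + ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                    y = "Mean intensity (normalized)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Full univariate profile for a dataset
#'
#' Convenience wrapper combining [t_test_per_wavenumber()],
#' [bh_correct()] and [auroc_per_wavenumber()] into one tidy table.
#'
#' @param dataset a [sers_dataset()].
#' @param variant t-test variant, see [t_test_per_wavenumber()].
#' @param fdr BH false discovery rate (default 0.05).
#' @return `univariate_profile` data.frame with the test columns plus
#'   `bh_significant` and `auroc`.
#' @export
univariate_profile <- function(dataset, variant = "welch", fdr = 0.05) {
  prof <- t_test_per_wavenumber(dataset, variant = variant)
  prof$bh_significant <- bh_correct(prof$p_value, fdr = fdr)
  prof$auroc <- auroc_per_wavenumber(dataset)
  attr(prof, "fdr") <- fdr
  prof
}
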