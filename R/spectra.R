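#' Labelled SERS spectra and aligned spectral datasets
#'
#' Two S3 containers carry the data through the pipeline.  A
#' `sers_spectrum` is a single sample: a strictly increasing wavenumber
#' axis (cm^-1), one intensity per wavenumber, and the sample metadata
#' (id, specimen, class label).  A `sers_dataset` is the aligned form all
#' analysis stages operate on: a samples x wavenumbers intensity matrix
#' on one shared grid, with per-sample labels.
#'
#' @param sample_id character scalar identifying the sample.
#' @param specimen `"plasma"` or `"serum"`.
#' @param label `"control"` or `"patient"`.
#' @param wavenumbers strictly increasing finite numeric vector (cm^-1),
#'   length >= 2.
#' @param intensities finite numeric vector, same length as `wavenumbers`.
#' @return `sers_spectrum()` returns an object of class `sers_spectrum`.
#' @examples
#' s <- sers_spectrum("s1", "plasma", "control", 400:410, rnorm(11))
#' s
#' @export
sers_spectrum <- function(sample_id, specimen, label, wavenumbers, intensities) {
  specimen <- match.arg(specimen, c("plasma", "serum"))
  label <- match.arg(label, c("control", "patient"))
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) < 2)
    stop_sers("spectrum '%s': needs at least 2 wavenumbers", sample_id,
              class = "sersdisc_parse_error")
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers)))
    stop_sers("spectrum '%s': non-finite wavenumbers", sample_id,
              class = "sersdisc_parse_error")
  d <- diff(wavenumbers)
  if (any(d <= 0)) {
    bad <- wavenumbers[which(d <= 0)[1] + 1]
    stop_sers("spectrum '%s': wavenumbers not strictly increasing at %g cm^-1",
              sample_id, bad, class = "sersdisc_parse_error")
  }
  if (length(intensities) != length(wavenumbers))
    stop_sers("spectrum '%s': %d intensities for %d wavenumbers", sample_id,
              length(intensities), length(wavenumbers),
              class = "sersdisc_parse_error")
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop_sers("spectrum '%s': non-finite intensities", sample_id,
              class = "sersdisc_parse_error")
  structure(list(sample_id = as.character(sample_id), specimen = specimen,
                 label = label, wavenumbers = wavenumbers,
                 intensities = intensities),
            class = "sers_spectrum")
}

#' @export
print.sers_spectrum <- function(x, ...) {
  cat(sprintf("<sers_spectrum> %s [%s, %s]: %d points, %g-%g cm^-1\n",
              x$sample_id, x$specimen, x$label, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' @rdname sers_spectrum
#' @param grid shared wavenumber grid (cm^-1), strictly increasing.
#' @param matrix numeric matrix, samples in rows, one column per grid node.
#' @param labels character/factor of `"control"`/`"patient"`, one per row.
#' @param sample_ids character vector, one per row (defaults to rownames
#'   or `s1, s2, ...`).
#' @param provenance list of recorded processing steps (internal).
#' @return `sers_dataset()` returns an object of class `sers_dataset` with
#'   fields `grid`, `matrix`, `labels`, `specimen`, `sample_ids`,
#'   `provenance`.
#' @export
sers_dataset <- function(grid, matrix, labels, specimen,
                         sample_ids = NULL, provenance = list()) {
  specimen <- match.arg(specimen, c("plasma", "serum"))
  grid <- as.numeric(grid)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(matrix)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(matrix)))
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("control", "patient")))
    stop_sers("labels must be 'control' or 'patient'",
              class = "sersdisc_parse_error")
  if (nrow(matrix) != length(labels) || nrow(matrix) != length(sample_ids))
    stop_sers("matrix has %d rows but %d labels and %d sample ids",
              nrow(matrix), length(labels), length(sample_ids),
              class = "sersdisc_parse_error")
  if (ncol(matrix) != length(grid))
    stop_sers("matrix has %d columns but grid has %d nodes",
              ncol(matrix), length(grid), class = "sersdisc_parse_error")
  if (any(diff(grid) <= 0))
    stop_sers("dataset grid must be strictly increasing",
              class = "sersdisc_parse_error")
  dimnames(matrix) <- list(sample_ids, NULL)
  structure(list(grid = grid, matrix = matrix, labels = labels,
                 specimen = specimen, sample_ids = as.character(sample_ids),
                 provenance = provenance),
            class = "sers_dataset")
}

#' @export
print.sers_dataset <- function(x, ...) {
  cat(sprintf("<sers_dataset> %s: %d samples (%d control, %d patient) x %d wavenumbers (%g-%g cm^-1)\n",
              x$specimen, nrow(x$matrix), sum(x$labels == "control"),
              sum(x$labels == "patient"), length(x$grid),
              min(x$grid), max(x$grid)))
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "step"),
                               collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.sers_dataset <- function(x) dim(x$matrix)

# Append one provenance record to a dataset.
record_step <- function(dataset, step, params = list()) {
  dataset$provenance <- c(dataset$provenance,
                          list(list(step = step, params = params)))
  dataset
}

#' Assemble aligned spectra into a dataset
#'
#' All spectra must already share an identical wavenumber grid (use
#' [resample_to_grid()] first otherwise) and a single specimen type.
#'
#' @param spectra list of [sers_spectrum()] objects.
#' @return a [sers_dataset()].
#' @export
spectra_to_dataset <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  grid <- spectra[[1]]$wavenumbers
  for (s in spectra) {
    if (length(s$wavenumbers) != length(grid) ||
        any(abs(s$wavenumbers - grid) > 1e-9))
      stop_sers("spectrum '%s' is not on the shared grid; resample first",
                s$sample_id, class = "sersdisc_parse_error")
  }
  specimen <- unique(vapply(spectra, `[[`, "", "specimen"))
  if (length(specimen) != 1)
    stop_sers("spectra mix specimen types: %s",
              paste(specimen, collapse = ", "),
              class = "sersdisc_parse_error")
  mat <- do.call(rbind, lapply(spectra, `[[`, "intensities"))
  sers_dataset(grid, mat,
               labels = vapply(spectra, `[[`, "", "label"),
               specimen = specimen,
               sample_ids = vapply(spectra, `[[`, "", "sample_id"))
}

#' Split a dataset back into spectra
#'
#' @param dataset a [sers_dataset()].
#' @return list of [sers_spectrum()] objects in row order.
#' @export
dataset_to_spectra <- function(dataset) {
  lapply(seq_len(nrow(dataset$matrix)), function(i) {
    sers_spectrum(dataset$sample_ids[i], dataset$specimen,
                  dataset$labels[i], dataset$grid, dataset$matrix[i, ])
  })
}
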