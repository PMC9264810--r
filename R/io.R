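#' Read labelled spectra from delimited text
#'
#' Two dialects are supported, both plain CSV/TSV (the delimiter is
#' auto-detected between comma and tab):
#'
#' * `"long"`: one row per (sample, wavenumber) with columns
#'   `sample_id`, `specimen`, `label`, `wavenumber`, `intensity`.
#' * `"wide"`: first column the wavenumber axis, one further column per
#'   sample; sample metadata (id, specimen, label) lives in a YAML or
#'   JSON sidecar file.
#'
#' @param path path to the spectral table.
#' @param format `"long"` or `"wide"`.
#' @param sidecar path to the metadata sidecar for `"wide"` files.  When
#'   `NULL`, `<path>.meta.yaml` then `<path>.meta.json` are tried.
#' @return list of [sers_spectrum()] records, in file order.
#' @seealso [write_spectra_table()]
#' @export
read_spectra_table <- function(path, format = c("long", "wide"),
                               sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_sers("file not found: %s", path, class = "sersdisc_io_error")
  sep <- detect_delimiter(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "long") read_long(tab) else read_wide(tab, path, sidecar)
}

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0)
    stop_sers("empty file: %s", path, class = "sersdisc_parse_error")
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab >= n_com) "\t" else ","
}

read_long <- function(tab) {
  need <- c("sample_id", "specimen", "label", "wavenumber", "intensity")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop_sers("long table lacks column(s): %s",
              paste(missing, collapse = ", "),
              class = "sersdisc_parse_error")
  ids <- unique(tab$sample_id)
  lapply(ids, function(id) {
    rows <- tab[tab$sample_id == id, , drop = FALSE]
    meta_sp <- unique(rows$specimen)
    meta_lb <- unique(rows$label)
    if (length(meta_sp) != 1 || length(meta_lb) != 1)
      stop_sers("sample '%s': inconsistent specimen/label across rows", id,
                class = "sersdisc_parse_error")
    if (anyNA(meta_lb) || !nzchar(meta_lb))
      stop_sers("sample '%s': missing label", id,
                class = "sersdisc_parse_error")
    check_duplicate_wavenumbers(rows$wavenumber, id)
    ord <- order(rows$wavenumber)
    sers_spectrum(id, meta_sp, meta_lb,
                  rows$wavenumber[ord], rows$intensity[ord])
  })
}

read_wide <- function(tab, path, sidecar) {
  meta <- read_sidecar(path, sidecar)
  wn <- tab[[1]]
  check_duplicate_wavenumbers(wn, basename(path))
  ids <- names(tab)[-1]
  known <- vapply(meta, `[[`, "", "sample_id")
  lapply(ids, function(id) {
    j <- match(id, known)
    if (is.na(j))
      stop_sers("sample '%s': no metadata entry in sidecar", id,
                class = "sersdisc_parse_error")
    sers_spectrum(id, meta[[j]]$specimen, meta[[j]]$label, wn, tab[[id]])
  })
}

check_duplicate_wavenumbers <- function(wn, who) {
  if (anyDuplicated(wn)) {
    dup <- wn[duplicated(wn)][1]
    stop_sers("'%s': duplicated wavenumber %g cm^-1", who, dup,
              class = "sersdisc_parse_error")
  }
}

read_sidecar <- function(path, sidecar) {
  if (is.null(sidecar)) {
    cands <- paste0(path, c(".meta.yaml", ".meta.json"))
    sidecar <- cands[file.exists(cands)][1]
    if (is.na(sidecar))
      stop_sers("no metadata sidecar found next to %s", path,
                class = "sersdisc_io_error")
  }
  if (!file.exists(sidecar))
    stop_sers("sidecar not found: %s", sidecar, class = "sersdisc_io_error")
  meta <- if (grepl("\\.json$", sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(sidecar)
  }
  if (!is.null(meta$samples)) meta <- meta$samples
  meta
}

#' Write labelled spectra to delimited text
#'
#' Inverse of [read_spectra_table()]; `read -> write -> read` reproduces
#' wavenumbers and intensities to full stored precision (values are
#' written with 17 significant digits) and all metadata exactly.
#'
#' @param spectra list of [sers_spectrum()] records.
#' @param path output path; extension `.csv` selects comma, otherwise tab.
#' @param format `"long"` (self-contained) or `"wide"` (writes a
#'   `<path>.meta.yaml` sidecar; all spectra must share one grid).
#' @return invisibly, the main file path.
#' @export
write_spectra_table <- function(spectra, path, format = c("long", "wide")) {
  format <- match.arg(format)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  if (format == "long") {
    tab <- do.call(rbind, lapply(spectra, function(s) {
      data.frame(sample_id = s$sample_id, specimen = s$specimen,
                 label = s$label, wavenumber = s$wavenumbers,
                 intensity = s$intensities, stringsAsFactors = FALSE)
    }))
    write_num_table(tab, path, sep)
  } else {
    grid <- spectra[[1]]$wavenumbers
    tab <- data.frame(wavenumber = grid, check.names = FALSE)
    for (s in spectra) {
      if (length(s$wavenumbers) != length(grid) ||
          any(s$wavenumbers != grid))
        stop_sers("wide format needs a shared grid; '%s' differs",
                  s$sample_id, class = "sersdisc_io_error")
      tab[[s$sample_id]] <- s$intensities
    }
    write_num_table(tab, path, sep)
    meta <- list(samples = lapply(spectra, function(s) {
      list(sample_id = s$sample_id, specimen = s$specimen, label = s$label)
    }))
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

write_num_table <- function(tab, path, sep) {
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Write an evaluation report table
#'
#' Emits a tab-separated table with one row per report and the column
#' layout `Sample, Accuracy, Precision, Sensitivity, Specificity,
#' True Pos., True Neg., False Pos., False Neg.`; percentages are
#' rendered with one decimal, rounding half up.
#'
#' @param report an `sers_evaluation` (from [loocv()]) or a list of them.
#' @param path output path.
#' @return invisibly, the formatted data.frame that was written.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "sers_evaluation")) report <- list(report)
  rows <- lapply(report, function(r) {
    cc <- r$confusion
    if (cc$tp + cc$tn + cc$fp + cc$fn == 0)
      stop_sers("empty evaluation: all confusion counts are zero",
                class = "sersdisc_report_error")
    m <- r$metrics
    data.frame(
      Sample = r$model_descriptor$dataset %||% "dataset",
      Accuracy = format_pct(m$accuracy), Precision = format_pct(m$precision),
      Sensitivity = format_pct(m$sensitivity),
      Specificity = format_pct(m$specificity),
      `True Pos.` = cc$tp, `True Neg.` = cc$tn,
      `False Pos.` = cc$fp, `False Neg.` = cc$fn,
      check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
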