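#' Analysis configuration
#'
#' Bundles every tunable of the full workflow.  The named band presets
#' mirror the three spectral windows the discrimination study design
#' uses: `full` (350-2200 cm^-1, the recorded window), `amide`
#' (1200-1700 cm^-1, the protein amide region), and `conclusions`
#' (825-1050 plus 1506-1750 cm^-1, the two intervals found most
#' informative).
#'
#' @param grid a [grid_spec()].
#' @param normalization `"snv"` (default, feeds the multivariate
#'   chain), `"area"`, or `"none"`.
#' @param bands named list of [band_spec()]s to evaluate.
#' @param methods list of [method_spec()]s.
#' @param fdr BH false discovery rate for the univariate profile.
#' @param vip_threshold VIP selection threshold.
#' @param baseline `NULL` (off, the default: instrument pipelines
#'   usually deliver baseline-corrected spectra) or a list with
#'   `lam`, `p_asym`, `iters` for [baseline_correct()].
#' @param cv list of cross-validation options
#'   (`refit_projection = TRUE`).
#' @param seed integer seed recorded in the provenance.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(grid = grid_spec(350, 2200, 1),
                            normalization = c("snv", "area", "none"),
                            bands = band_presets(),
                            methods = list(method_spec("pca_lda"),
                                           method_spec("plsda"),
                                           method_spec("pca_svm")),
                            fdr = 0.05, vip_threshold = 1.0,
                            baseline = NULL,
                            cv = list(refit_projection = TRUE),
                            seed = 1) {
  normalization <- match.arg(normalization)
  stopifnot(fdr > 0, fdr < 1, length(bands) >= 1, !is.null(names(bands)))
  structure(list(grid = grid, normalization = normalization, bands = bands,
                 methods = methods, fdr = fdr,
                 vip_threshold = vip_threshold, baseline = baseline,
                 cv = cv, seed = as.integer(seed)),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @export
band_presets <- function() {
  list(full = band_spec(list(c(350, 2200))),
       amide = band_spec(list(c(1200, 1700))),
       conclusions = band_spec(list(c(825, 1050), c(1506, 1750))))
}

#' Run the full discrimination workflow
#'
#' Orchestrates the complete analysis: preprocessing (resampling if
#' spectra are supplied, optional baseline correction, normalization),
#' one LOOCV evaluation per (method x band) pair, and -- once per
#' dataset, on the first configured band -- the univariate profile
#' (Welch t + BH mask + AUROC), the VIP profile from a PLS-DA fit,
#' significant band runs, and the annotated mean-spectrum summary.
#' Outputs carry a provenance record sufficient to re-run the analysis
#' bit-identically.
#'
#' @param x a [sers_dataset()], a list of [sers_spectrum()]s (resampled
#'   onto `config$grid`), or a [cohort_spec()] (simulated first).
#' @param config an [analysis_config()].
#' @param out_dir optional directory; when given, report tables
#'   (`reports.tsv`), the univariate profile (`univariate.tsv`),
#'   per-fold predictions (`folds.json`) and provenance
#'   (`provenance.json`) are written there.
#' @return list of class `sers_analysis` with `reports` (named
#'   `"method/band"`), `univariate`, `vip`, `significant_runs`,
#'   `vip_runs`, `mean_summary`, `dataset` (preprocessed), and
#'   `provenance`.
#' @export
run_full_analysis <- function(x, config = analysis_config(),
                              out_dir = NULL) {
  if (inherits(x, "cohort_spec")) {
    dataset <- simulate_cohort(x)
  } else if (inherits(x, "sers_dataset")) {
    dataset <- x
  } else if (is.list(x) && all(vapply(x, inherits, TRUE, "sers_spectrum"))) {
    dataset <- spectra_to_dataset(
      lapply(x, resample_to_grid, grid = config$grid))
  } else {
    stop_sers("input must be a dataset, spectra list, or cohort spec",
              class = "sersdisc_input_error")
  }
  input_digest <- object_digest(unclass(dataset[c("grid", "matrix",
                                                  "labels")]))
  if (!is.null(config$baseline)) {
    bl <- config$baseline
    spectra <- lapply(dataset_to_spectra(dataset), baseline_correct,
                      lam = bl$lam %||% 1e5, p_asym = bl$p_asym %||% 0.01,
                      iters = bl$iters %||% 10)
    prov_steps <- dataset$provenance
    dataset <- spectra_to_dataset(spectra)
    dataset$provenance <- prov_steps
    dataset <- record_step(dataset, "baseline_correct", bl)
  }
  dataset <- switch(config$normalization,
                    snv = snv_normalize(dataset),
                    area = area_normalize(dataset),
                    none = dataset)

  reports <- list()
  for (band_name in names(config$bands)) {
    sub <- restrict_band(dataset, config$bands[[band_name]])
    attr(sub, "band_name") <- band_name
    for (m in config$methods) {
      rep <- loocv(sub, m,
                   refit_projection = config$cv$refit_projection %||% TRUE)
      reports[[paste(m$method, band_name, sep = "/")]] <- rep
    }
  }

  uni_band <- names(config$bands)[1]
  uni_ds <- restrict_band(dataset, config$bands[[uni_band]])
  prof <- univariate_profile(uni_ds, fdr = config$fdr)
  pls <- plsda_fit(uni_ds$matrix, uni_ds$labels, n_components = 2)
  vip <- vip_scores(pls, wavenumber = uni_ds$grid,
                    threshold = config$vip_threshold)
  runs_bh <- significant_bands(prof$bh_significant, uni_ds$grid)
  runs_vip <- significant_bands(vip$vip > vip$threshold, uni_ds$grid)
  summary <- mean_spectra_with_annotations(uni_ds, prof, vip)

  provenance <- list(
    package = "sersdisc",
    version = as.character(utils::packageVersion("sersdisc")),
    input_digest = input_digest,
    seed = config$seed,
    config = serialize_config(config),
    steps = dataset$provenance)

  out <- structure(list(reports = reports, univariate = prof, vip = vip,
                        significant_runs = runs_bh, vip_runs = runs_vip,
                        mean_summary = summary, dataset = dataset,
                        provenance = provenance),
                   class = "sers_analysis")
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

serialize_config <- function(config) {
  list(grid = unclass(config$grid),
       normalization = config$normalization,
       bands = lapply(config$bands, function(b) b$intervals),
       methods = lapply(config$methods, unclass),
       fdr = config$fdr, vip_threshold = config$vip_threshold,
       baseline = config$baseline, cv = config$cv, seed = config$seed)
}

write_analysis <- function(analysis, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(analysis$reports, file.path(out_dir, "reports.tsv"))
  uni <- analysis$univariate
  uni$vip <- analysis$vip$vip
  uni$vip_gt_1 <- analysis$vip$vip > analysis$vip$threshold
  uni$auroc <- analysis$univariate$auroc
  cols <- c("wavenumber", "t_stat", "p_value", "bh_significant", "vip",
            "vip_gt_1", "auroc", "mean_control", "mean_patient")
  utils::write.table(as.data.frame(uni)[, cols],
                     file.path(out_dir, "univariate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  folds <- lapply(analysis$reports, function(r) r$per_fold_predictions)
  jsonlite::write_json(folds, file.path(out_dir, "folds.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  jsonlite::write_json(analysis$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(out_dir)
}

#' @export
print.sers_analysis <- function(x, ...) {
  cat(sprintf("<sers_analysis> %d evaluation reports, %d BH-significant runs, %d VIP runs\n",
              length(x$reports), nrow(x$significant_runs),
              nrow(x$vip_runs)))
  for (r in x$reports) print(r)
  invisible(x)
}

#' Compare two evaluation reports metric by metric
#'
#' Side-by-side metric deltas (second minus first), e.g. serum minus
#' plasma for the same discrimination method.  Reports fitted with
#' different methods are not comparable and raise an error.
#'
#' @param report_a,report_b `sers_evaluation` objects from [loocv()]
#'   with the same `method`.
#' @return data.frame with `metric`, `a`, `b`, `delta` (percent points).
#' @export
compare_specimens <- function(report_a, report_b) {
  da <- report_a$model_descriptor; db <- report_b$model_descriptor
  if (!identical(da$method, db$method) ||
      !identical(da$n_components, db$n_components))
    stop_sers("reports use different methods (%s vs %s); not comparable",
              da$method, db$method, class = "sersdisc_input_error")
  metrics <- c("accuracy", "precision", "sensitivity", "specificity")
  a <- unlist(report_a$metrics[metrics])
  b <- unlist(report_b$metrics[metrics])
  data.frame(metric = metrics, a = unname(a), b = unname(b),
             delta = unname(b - a))
}
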