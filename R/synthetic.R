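#' Peak and cohort specifications for synthetic SERS spectra
#'
#' `peak_spec()` describes one vibrational band: a Lorentzian (default)
#' or Gaussian line with a base amplitude shared by both classes and a
#' multiplicative `class_effect` applied to patients (`> 1` patient-up,
#' `< 1` patient-down, `1` null).  `patient_only = TRUE` marks a band
#' absent from control spectra altogether (its amplitude is zero for
#' controls).
#'
#' @param center band center in cm^-1.
#' @param base_amplitude nonnegative amplitude in arbitrary units.
#' @param class_effect positive multiplicative patient effect.
#' @param width half-width at half-maximum in cm^-1 (default 8).
#' @param shape `"lorentzian"` (default) or `"gaussian"`.
#' @param patient_only if `TRUE`, the band only appears in patients.
#' @return list of class `peak_spec`.
#' @export
peak_spec <- function(center, base_amplitude, class_effect = 1,
                      width = 8, shape = c("lorentzian", "gaussian"),
                      patient_only = FALSE) {
  shape <- match.arg(shape)
  stopifnot(width > 0, base_amplitude >= 0, class_effect > 0)
  structure(list(center = center, base_amplitude = base_amplitude,
                 class_effect = class_effect, width = width,
                 shape = shape, patient_only = patient_only),
            class = "peak_spec")
}

#' @rdname peak_spec
#' @param n_control,n_patient cohort sizes.
#' @param grid a [grid_spec()] (default 350-2200 cm^-1 at 1 cm^-1).
#' @param peaks list of [peak_spec()]s.
#' @param baseline_amp amplitude of the random degree-3 polynomial
#'   baseline (same units as peak amplitudes).
#' @param scatter_sd log-sd of the per-spectrum multiplicative gain.
#' @param noise_sd sd of additive per-node noise.
#' @param jitter_sd sd (cm^-1) of the per-spectrum peak-position shift.
#' @param amplitude_cv log-sd of the per-spectrum, per-peak lognormal
#'   amplitude variability.
#' @param seed integer seed; all randomness in [simulate_cohort()] flows
#'   from it.
#' @return `cohort_spec()`: list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control, n_patient, peaks,
                        grid = grid_spec(350, 2200, 1),
                        baseline_amp = 0.1, scatter_sd = 0.05,
                        noise_sd = 0.02, jitter_sd = 0.5,
                        amplitude_cv = 0.15, seed = 1) {
  stopifnot(n_control >= 0, n_patient >= 0, baseline_amp >= 0,
            scatter_sd >= 0, noise_sd >= 0, jitter_sd >= 0,
            amplitude_cv >= 0)
  structure(list(n_control = n_control, n_patient = n_patient,
                 grid = grid, peaks = peaks, baseline_amp = baseline_amp,
                 scatter_sd = scatter_sd, noise_sd = noise_sd,
                 jitter_sd = jitter_sd, amplitude_cv = amplitude_cv,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Shared effect magnitudes for the presets: patients-up bands are scaled
# by 1.3, patients-down bands by 0.77.
.EFF_UP <- 1.3
.EFF_DOWN <- 0.77

#' Plasma-like synthetic cohort preset
#'
#' Twenty vibrational bands typical of blood-plasma SERS spectra, with
#' the strongest signals at 642, 1136 and 1662 cm^-1.  Patients are
#' attenuated (effect 0.77) at 1256, 1336, 1508, 1617 and 1662 cm^-1
#' and elevated (effect 1.3) at 1010 and 1209 cm^-1; the remaining
#' bands carry no class effect.  Cohort sizes default to 14 controls
#' and 27 patients.
#'
#' @param seed integer seed stored in the spec.
#' @param specimen attached to generated datasets (`"plasma"`).
#' @return a [cohort_spec()].
#' @export
preset_plasma <- function(seed = 1) {
  up <- .EFF_UP; dn <- .EFF_DOWN
  tab <- list(
    #            center  amp   effect
    c(390, 0.45, 1), c(498, 0.35, 1), c(596, 0.30, 1), c(642, 1.00, 1),
    c(728, 0.35, 1), c(815, 0.30, 1), c(893, 0.30, 1), c(1010, 0.45, up),
    c(1075, 0.35, 1), c(1136, 0.95, 1), c(1209, 0.40, up),
    c(1256, 0.40, dn), c(1336, 0.45, dn), c(1369, 0.35, 1),
    c(1406, 0.35, 1), c(1447, 0.40, 1), c(1508, 0.40, dn),
    c(1577, 0.40, 1), c(1617, 0.45, dn), c(1662, 0.90, dn))
  peaks <- lapply(tab, function(r) peak_spec(r[1], r[2], r[3]))
  spec <- cohort_spec(n_control = 14, n_patient = 27, peaks = peaks,
                      seed = seed)
  spec$specimen <- "plasma"
  spec
}

#' Serum-like synthetic cohort preset
#'
#' The plasma band inventory adapted to serum, plus a patient-only band
#' at 1099 cm^-1 (absent from control spectra).  Patients are elevated
#' (effect 1.3) at 498, 642, 815, 893, 1010, 1137, 1210, 1368 and
#' 1412 cm^-1 and attenuated (effect 0.77) at 728, 1331, 1447, 1506,
#' 1582 and 1660 cm^-1.  Cohort sizes default to 14 controls and 29
#' patients.
#'
#' @inheritParams preset_plasma
#' @return a [cohort_spec()].
#' @export
preset_serum <- function(seed = 1) {
  up <- .EFF_UP; dn <- .EFF_DOWN
  tab <- list(
    c(390, 0.45, 1), c(498, 0.35, up), c(596, 0.30, 1), c(642, 1.00, up),
    c(728, 0.35, dn), c(815, 0.30, up), c(893, 0.30, up),
    c(1010, 0.45, up), c(1075, 0.35, 1), c(1137, 0.95, up),
    c(1210, 0.40, up), c(1256, 0.40, 1), c(1331, 0.45, dn),
    c(1368, 0.35, up), c(1412, 0.35, up), c(1447, 0.40, dn),
    c(1506, 0.40, dn), c(1582, 0.40, dn), c(1617, 0.45, 1),
    c(1660, 0.90, dn))
  peaks <- lapply(tab, function(r) peak_spec(r[1], r[2], r[3]))
  peaks <- append(peaks, list(peak_spec(1099, 0.40, 1, patient_only = TRUE)),
                  after = 9)  # keep centers sorted
  spec <- cohort_spec(n_control = 14, n_patient = 29, peaks = peaks,
                      seed = seed)
  spec$specimen <- "serum"
  spec
}

#' Scale all class effects of a cohort spec
#'
#' Raises every `class_effect` (and implicitly the patient-only bands'
#' presence, which is left untouched) to the power `exponent`, moving
#' effects toward the null for `exponent < 1`.  Used to study
#' performance at reduced effect sizes.
#'
#' @param spec a [cohort_spec()].
#' @param exponent nonnegative power applied to each `class_effect`.
#' @return the modified spec.
#' @export
scale_class_effects <- function(spec, exponent) {
  stopifnot(exponent >= 0)
  spec$peaks <- lapply(spec$peaks, function(p) {
    p$class_effect <- p$class_effect^exponent
    p
  })
  spec
}

line_shape <- function(w, center, width, shape) {
  if (shape == "lorentzian") {
    width^2 / ((w - center)^2 + width^2)
  } else {
    s <- width / sqrt(2 * log(2))
    exp(-(w - center)^2 / (2 * s^2))
  }
}

#' Simulate a labelled synthetic cohort
#'
#' Each spectrum is a sum of its class's bands with per-spectrum
#' lognormal amplitude variability and a shared small random position
#' jitter, plus a slowly varying random degree-3 polynomial baseline;
#' the sum is scaled by a lognormal multiplicative gain and corrupted
#' by additive Gaussian noise at every grid node.
#'
#' All randomness flows from `spec$seed`: the generator seeds a local
#' RNG stream and draws, per sample in order (controls first, then
#' patients), the gain, the position jitter, the 4 baseline
#' coefficients, the per-peak amplitude factors, and finally the noise
#' vector.  The same spec therefore yields a bit-identical dataset on
#' every call, and the caller's RNG state is untouched.
#'
#' @param spec a [cohort_spec()].
#' @return a [sers_dataset()] (specimen from the preset, `"plasma"` if
#'   unset) with rows `ctl01...` then `pat01...`.
#' @export
simulate_cohort <- function(spec) {
  nodes <- grid_nodes(spec$grid)
  n <- spec$n_control + spec$n_patient
  labels <- rep(c("control", "patient"), c(spec$n_control, spec$n_patient))
  ids <- c(sprintf("ctl%02d", seq_len(spec$n_control)),
           sprintf("pat%02d", seq_len(spec$n_patient)))
  centers <- vapply(spec$peaks, `[[`, 0, "center")
  widths <- vapply(spec$peaks, `[[`, 0, "width")
  shapes <- vapply(spec$peaks, `[[`, "", "shape")
  bases <- vapply(spec$peaks, `[[`, 0, "base_amplitude")
  effects <- vapply(spec$peaks, `[[`, 0, "class_effect")
  ponly <- vapply(spec$peaks, `[[`, TRUE, "patient_only")
  k <- length(spec$peaks)
  u <- seq(0, 1, length.out = length(nodes))
  mat <- with_local_seed(spec$seed, {
    m <- matrix(0, n, length(nodes))
    for (i in seq_len(n)) {
      gain <- exp(stats::rnorm(1, 0, spec$scatter_sd))
      delta <- stats::rnorm(1, 0, spec$jitter_sd)
      bcoef <- stats::rnorm(4)
      afac <- exp(stats::rnorm(k, 0, spec$amplitude_cv))
      is_pat <- labels[i] == "patient"
      amp <- bases * (if (is_pat) effects else rep(1, k)) * afac
      if (!is_pat) amp[ponly] <- 0
      signal <- numeric(length(nodes))
      for (j in seq_len(k)) {
        if (amp[j] == 0) next
        signal <- signal + amp[j] *
          line_shape(nodes, centers[j] + delta, widths[j], shapes[j])
      }
      baseline <- spec$baseline_amp *
        (bcoef[1] + bcoef[2] * u + bcoef[3] * u^2 + bcoef[4] * u^3)
      noise <- stats::rnorm(length(nodes), 0, spec$noise_sd)
      m[i, ] <- (signal + baseline) * gain + noise
    }
    m
  })
  ds <- sers_dataset(nodes, mat, labels, spec$specimen %||% "plasma",
                     sample_ids = ids)
  record_step(ds, "simulate_cohort", list(seed = spec$seed))
}

#' Simulate a matched null cohort
#'
#' Identical generative process to [simulate_cohort()] but with every
#' `class_effect` forced to 1 and patient-only bands removed, so the
#' patient and control populations are exchangeable while the labels
#' are retained.  Used for false-discovery-rate and null-performance
#' checks.
#'
#' @param spec a [cohort_spec()].
#' @return a [sers_dataset()].
#' @export
null_cohort <- function(spec) {
  spec$peaks <- Filter(function(p) !p$patient_only, spec$peaks)
  spec$peaks <- lapply(spec$peaks, function(p) {
    p$class_effect <- 1
    p
  })
  simulate_cohort(spec)
}

#' Centers of the discriminative bands of a cohort spec
#'
#' @param spec a [cohort_spec()].
#' @return numeric vector of centers with `class_effect != 1` or
#'   `patient_only = TRUE` -- the planted ground truth that recovery
#'   checks test against.
#' @export
planted_peak_centers <- function(spec) {
  keep <- vapply(spec$peaks, function(p)
    p$class_effect != 1 || p$patient_only, TRUE)
  vapply(spec$peaks[keep], `[[`, 0, "center")
}
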