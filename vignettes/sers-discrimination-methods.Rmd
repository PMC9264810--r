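---
title: "Methods: chemometric discrimination of blood-derived SERS spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometric discrimination of blood-derived SERS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersdisc)
```

## The problem

Surface-enhanced Raman spectroscopy (SERS) of blood plasma and serum
produces, per sample, an intensity curve over Raman shifts of roughly
350–2200 cm⁻¹.  Cancer patients and healthy donors yield *almost*
identical curves: individual band intensities carry weak, unspecific
signal, so the discriminating information has to be pulled out of the
whole spectrum at once.  `sersdisc` implements the standard chemometric
answer — dimensionality reduction followed by a linear decision rule,
validated by leave-one-out cross-validation (LOOCV) — together with a
complementary per-wavenumber univariate analysis, and a synthetic
spectrum generator that lets every stage be tested end to end without
access to patient data.

Throughout the package the positive class is `patient`, so sensitivity
is the detection rate among patients and specificity the rate of
correctly cleared controls.

## Preprocessing

Spectra are first aligned by linear interpolation onto a common grid at
1 cm⁻¹ spacing (`resample_to_grid()`).  Linear interpolation is the
minimal-assumption choice given instrument resolution of ~2 cm⁻¹;
anything higher-order would be inventing curvature between support
points.

The multivariate chain then applies the standard normal variate
transform (`snv_normalize()`): each spectrum is offset and scaled to
zero mean and unit standard deviation, cancelling per-spectrum
multiplicative scatter (laser/substrate gain) and additive offset.  We
use the sample standard deviation (denominator *n − 1*); with ~1800
grid points the distinction from the population form is a common
factor of ~1.0003 per spectrum and affects nothing downstream, but the
choice is recorded and switchable.  Area normalization to unit
integral over 350–2200 cm⁻¹ (`area_normalize()`) is retained for
figure-style mean spectra, where curves are compared visually.

Baseline correction by asymmetric least squares is available
(`baseline_correct()`: second-difference penalty `lam`, default 1e5;
asymmetry `p_asym = 0.01`; 10 reweighting iterations) but **off by
default**: vendor acquisition software typically delivers
fluorescence-corrected spectra, and correcting twice distorts peak
heights.  The generator still produces a residual polynomial drift so
the corrector has realistic work in tests.

Analyses can be restricted to closed wavenumber windows
(`restrict_band()`, endpoints inclusive).  Three presets are built in:
`full` (350–2200), `amide` (1200–1700, the protein amide I/III
region), and `conclusions` (825–1050 ∪ 1506–1750, the two windows that
prove most informative for serum).

## Multivariate models

All three classifier chains are linear, deterministic, and fitted from
scratch inside every cross-validation fold.

**PCA–LDA.** PCA is computed by SVD of the centered matrix rather than
an eigendecomposition of the covariance — identical in exact
arithmetic, better conditioned for wide spectral matrices.  Component
signs are fixed by making each loading's largest-magnitude entry
positive, so fits are reproducible to the bit.  Two components are the
default everywhere: small cohorts (41–43 samples) cannot support many
more without overfitting, as the train/LOOCV gap diagnostic below
makes measurable.  The Fisher discriminant uses the pooled
within-class scatter with an automatic ridge of
`1e-8 · trace(S_w)/d` — zero in exact arithmetic terms, but enough to
survive degenerate folds; when a fold's scatter vanishes entirely the
ridge falls back to the class-separation scale, which turns the rule
into nearest-means.  The decision threshold is the equal-posterior
point of the two projected class Gaussians under shared variance and
empirical priors; exact ties go to the larger prior and to `control`
at equal priors.

**PLS-DA.** NIPALS PLS1 against the centered 0/1 class indicator, two
latent components, X deflated per component.  The ±1 indicator coding
sometimes used elsewhere is an affine transform of ours and produces
identical assignments; the decision cut is the coding midpoint 0.5.
Variable importance in projection (Wold's VIP) weights each
wavenumber's squared loading-weight by the y-variance its component
explains; `sum(VIP²) = p` by construction, and VIP > 1 is the
conventional "more than average contribution" selection rule.

**PCA–SVM.** A linear soft-margin SVM (cost 1.0 by default — no
hyperparameter search, deliberately) on the 2 PC scores.  The solver
is deterministic dual coordinate descent with the bias absorbed as an
augmented feature, so the dual has box constraints only; the stopping
tolerance on the projected gradient scales with the mean squared
sample norm to remain attainable in floating point at any score
magnitude.

## Validation

`loocv()` refits the **entire** chain — projection included — on every
fold of *n − 1* samples.  Refitting only the discriminant while the
projection sees all data is a common shortcut and is available as
`refit_projection = FALSE` for sensitivity analysis, but it leaks the
held-out spectrum into the subspace and is stamped as such in every
report.  A dedicated test plants an extreme outlier and verifies its
own fold model is bit-identical to one fitted on clean data.

Confusion counts keep `patient` positive; metrics are held as exact
ratios and only rounded (half-up, one decimal) at presentation.
Ratios with zero denominators are reported as explicitly unavailable,
never as 0.

`train_test_gap()` sweeps the component count and reports mean
training-fold accuracy next to LOOCV accuracy.  At 2 components the
two nearly coincide on these cohort sizes; at 10 components the gap
roughly triples — the quantitative justification for the 2-component
default.

## Univariate analysis

`t_test_per_wavenumber()` tests each grid node independently; Welch's
unequal-variance form is the default because the cohorts are
unbalanced (14 vs 27/29) — the pooled Student form is a switch.
Columns with zero variance in both groups are untestable and flagged
rather than silently given p = 0 or 1e-300.  Multiplicity is handled
by Benjamini–Hochberg step-up at FDR 5% (`bh_correct()`, delegated to
`p.adjust`).  Per-wavenumber AUROC uses the Mann–Whitney rank identity
with midrank ties.  `significant_bands()` collapses significance
masks into maximal runs and discards runs under 3 grid nodes — a
1 cm⁻¹-wide "significant band" is a sampling artifact, not chemistry.

Peak detection in the mean-spectrum summaries uses local maxima with
topographic prominence of at least 2% of the curve's intensity range;
class-wise and grouped mean spectra can legitimately disagree about
peak positions when class means are shifted, so both lists are
reported.

## The synthetic generator

`simulate_cohort()` emulates the structure of blood-derived SERS
spectra: a sum of Lorentzian bands (natural Raman line shape; default
half-width 8 cm⁻¹, narrow enough that the 1136/1209 cm⁻¹ pair stays
resolved at 1 cm⁻¹ sampling) with

* per-spectrum, per-band lognormal amplitude variability (cv 0.15),
* one shared position jitter per spectrum (sd 0.5 cm⁻¹),
* a random degree-3 polynomial baseline (amplitude 0.1 in peak units,
  emulating residual drift after vendor correction),
* a lognormal multiplicative gain (log-sd 0.05), and
* additive Gaussian noise (sd 0.02, ~2% of the strongest band).

The `plasma` preset plants 20 bands with the strongest at 642, 1136
and 1662 cm⁻¹; patients are attenuated ×0.77 at 1256, 1336, 1508,
1617 and 1662 cm⁻¹ and elevated ×1.3 at 1010 and 1209 cm⁻¹ (14
controls, 27 patients).  The `serum` preset additionally plants a
patient-only band at 1099 cm⁻¹ and carries nine patient-up and six
patient-down bands (14 controls, 29 patients).  Reported behaviour of
the serum band near 1099–1100 cm⁻¹ is ambiguous in the literature
(described both as appearing only in patients and as elevated in
controls); the preset adopts the patient-only reading — the one tied
to the spectra themselves rather than to summary band lists — and
records the ambiguity here instead of averaging it away.

Effect magnitudes 1.3/0.77 place the presets in the regime the method
is designed for: with these defaults PCA-LDA LOOCV accuracy averages
in the high 80s (%) on plasma and saturates near 100% on serum —
mirroring the qualitative plasma-worse-than-serum ordering without
claiming to reproduce any particular cohort.  `scale_class_effects()`
shrinks every effect toward the null for sensitivity studies;
`null_cohort()` removes all of them (and the patient-only band) while
keeping labels, giving exchangeable classes for FDR and
null-performance checks.

All randomness flows from the single spec seed through a documented
per-sample draw order (gain, jitter, baseline coefficients, amplitude
factors, noise), so a spec is a complete, bit-reproducible description
of a cohort, and the caller's RNG state is never touched.

**What the generator does not emulate:** substrate-to-substrate
enhancement variability, analyte-competition effects (e.g. dietary
ergothioneine dominating the spectrum), detector spikes, wavelength
miscalibration, or any correlation structure between neighbouring
bands beyond line-shape overlap.  Passing tests on these cohorts
therefore demonstrate the *statistical machinery* — leakage-free
validation, FDR control, recovery of planted effects — not clinical
performance on real spectra.

## Numerical choices and degenerate inputs

* Band endpoints are inclusive; grids are validated to 1e-9.
* Constant spectra are rejected by SNV (sd = 0) and area
  normalization (area ≤ 0) with the sample named.
* PCA refuses components beyond the numerical rank
  (`max(dim) · eps · σ₁` threshold).
* NIPALS caps at 500 iterations at tolerance 1e-10 (one pass suffices
  for a single response); exhausting X's rank raises an error rather
  than returning junk components.
* The SVM solver caps at 1e6 sweeps; non-convergence is an error, not
  a warning.
* LOOCV on a dataset where a fold would lose an entire class names the
  offending sample.

## Problem sizes used by the test-suite simulations

Property-style checks run at the cohort sizes above: 200 replicates of
500-column null cohorts for FDR control, 25 seeds for planted-band
recovery and for the overfitting diagnostic, 50 seeds for VIP peak
flagging, three effect levels × 25 seeds for effect-size monotonicity.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted margins while keeping the default test run fast.

## Known limitations

* Only two-class problems; no multi-class discrimination.
* Only linear kernels and linear discriminants — by design, matching
  the validated workflow.
* The univariate stage treats wavenumbers independently; no
  cluster-based or permutation multiplicity control.
* LOOCV metrics on 41–43 samples have wide confidence bands; the
  package reports counts so users can compute them, but does not
  pretend the point estimates are precise.
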