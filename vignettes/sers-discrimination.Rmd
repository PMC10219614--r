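---
title: "Discriminating two-group SERS cohorts: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating two-group SERS cohorts: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sersdx)
library(dplyr)
```

## The problem

Surface-enhanced Raman spectroscopy (SERS) of biofluids — here, exosomes
isolated from saliva and dried onto a silver plasmonic substrate — yields
per-sample spectra whose vibrational bands report on the protein, lipid,
nucleic-acid and small-molecule content of the analyte. In a two-group
(cancer vs. control) cohort design, the analysis questions are:

1. at which wavenumbers do the group mean intensities differ
   (pointwise testing with false-discovery-rate control), and
2. how well can a sample's group be predicted from its whole spectrum
   (PCA--LDA classification under leave-one-out cross-validation, scored
   by confusion-matrix metrics and AUROC),

asked both on the full acquisition range (350--2350 cm⁻¹) and on a
restricted window (2000--2200 cm⁻¹) around the dominant thiocyanate
−C≡N stretch at 2110 cm⁻¹, a band of particular diagnostic interest
because — unlike most protein and nucleic-acid bands, which are elevated
in cancer — it is roughly twice as intense in controls.

`sersdx` implements this pipeline end to end, together with a synthetic
cohort generator so that every stage is testable without access to any
particular study's raw spectra.

## Data model

Everything is a data frame. A *spectrum* is a tibble with `wavenumber`
(cm⁻¹, strictly increasing) and `intensity` (a.u.) columns; a *cohort*
is a long tibble adding `sample_id`, `group` (`cancer`/`control`) and
`replicate`; the *analysis matrix* from `cohort_matrix()` is a wide
tibble with one row per sample and one column per grid wavenumber.
`restrict_range()` applies a closed wavenumber interval to either shape;
windows are closed (`[2000, 2200]` keeps both endpoints, 101 points on
the 2 cm⁻¹ grid). Spectrum files are two-column delimited text with `#`
comments (comma, tab or whitespace on input; comma on output, written at
full precision so round-trips are exact); cohorts are a manifest CSV
(`sample_id,group,spectrum_path`). Duplicate wavenumbers are an error —
silently averaging them would mask acquisition faults.

## The synthetic cohort generator

`simulate_cohort()` emulates the acquisition design the pipeline
targets: 29 cancer and 22 control subjects, 100 replicate acquisitions
per sample (reducible; the package's own simulation studies use 5 for
speed) on the 350--2350 cm⁻¹ / 2 cm⁻¹ grid. Each replicate is

```
gain × [ Σ_b amp_b(group, sample) · Lorentzian(w; center_b, fwhm_b) + baseline(w) ] + noise
```

with, per band `b`, `amp_b = base_amplitude · cancer_multiplier^(group
== cancer) · sample_effect_b`:

* **Band profile.** Lorentzian (the natural Raman line shape), FWHM
  12 cm⁻¹ for all 20 bands of `default_peak_table()`. Amplitudes are
  chosen so the 2110 cm⁻¹ thiocyanate band dominates the spectrum, with
  the remaining bands between 1 and 2.5 a.u.
* **Effect structure.** `cancer_multiplier > 1` (1.25--1.4) for every
  band except the two thiocyanate bands: 443 cm⁻¹ (0.7) and 2110 cm⁻¹
  (0.5, i.e. control mean ≈ 2× cancer mean). Only the directions and
  the ≈2× ratio at 2110 are anchored in the study design this package
  addresses; the amplitudes and multipliers are generator settings, not
  estimates of any real cohort, and downstream accuracies on synthetic
  cohorts must not be read as estimates of real-data performance.
* **Fluorescence background.** A broad decaying exponential plus a
  gentle quadratic, scale `baseline_amplitude` (default 5 a.u.) —
  typical of NIR-excited biofluid measurements.
* **Noise and artifacts.** Additive Gaussian detector noise
  (`noise_sd = 0.1`), per-replicate log-normal gain (`gain_sd = 0.2`;
  exactly the multiplicative variation SNV is designed to remove, which
  makes SNV's effect testable), and with probability 0.05 per replicate
  one cosmic-ray spike, 1--3 grid points wide and 30 a.u. high (≫ 10×
  the noise sd, so despiking is detectable).
* **Biological variability.** Per-sample, per-band log-normal random
  effects with `between_sample_sd = 0.15`.

Identical configurations (including `seed`) give bit-identical cohorts,
and the caller's RNG state is untouched. What the generator does *not*
model: plasmonic enhancement physics, laser/instrument drift, band
position shifts, correlated (pink) noise, or any particle-size
distribution of the vesicles. Tests passing on synthetic cohorts
demonstrate that the statistical machinery is correct and calibrated;
they say nothing about how discriminable real cancer and control saliva
samples are.

## Preprocessing

The fixed per-sample order is: despike each replicate → subtract its
baseline → resample it to the uniform grid → average replicates → SNV.
Order matters (tests guard against silent reordering: SNV before
averaging gives a measurably different result).

* **Despiking** uses the modified z-score of first-differenced
  intensities (Whitaker--Hayes style), threshold 8; flagged points are
  replaced by the median of the nearest unflagged neighbours within a
  5-point window. The scale estimate is the MAD of the differences, so
  in the *zero-noise limit* the method degenerates: with no detector
  noise the MAD collapses and the steep flanks of real bands are
  flagged. This is inherent to any spike detector that estimates its
  scale from the spectrum itself. `despike_z_threshold = Inf` disables
  the stage for noise-free simulated input; at the default threshold
  under realistic noise the dominant band top survives intact (tested).
* **Baseline removal** is asymmetric least squares (Eilers-type):
  minimise `Σ w_i (y_i − z_i)² + λ Σ (Δ²z)²` with `w_i = p` above the
  baseline and `1 − p` below, λ = 10⁵, p = 0.01, 10 reweighting
  iterations (early exit once the weights stabilise; if they never do,
  the last iterate is used with a warning). The normal matrix is
  pentadiagonal, so the solver is an O(n) banded Cholesky in C++,
  verified against a dense reference solve. Two intrinsic distortions
  are documented and tested rather than hidden: AsLS infers a small
  positive background under the broad Lorentzian flanks of a strong
  band even when none exists (≈2% of the dominant peak height at
  λ = 10⁵), and where many bands overlap their common continuum is
  partly absorbed into the baseline. Both affect the two groups alike.
  `baseline = FALSE` skips the stage for data known to carry no
  background.
* **Resampling** is linear interpolation onto the closed uniform grid
  (350--2350 cm⁻¹ step 2 → exactly 1001 points), exact on affine
  signals and on on-grid input points. No extrapolation, ever: a grid
  outside the input support is an error, not a guess. Resampling is
  applied per replicate *before* averaging so heterogeneous acquisition
  grids are supported; when replicates already share the target grid it
  is a no-op.
* **SNV** subtracts the spectrum mean and divides by its sd (n−1
  denominator), making each processed spectrum invariant to the
  replicate gain and any additive offset. A zero-variance spectrum is
  an error naming the sample.

## Univariate stage

`run_univariate()` performs one two-sided test per grid wavenumber on
the processed matrix. The default is Welch's unequal-variance t-test
(group sizes 29 vs 22 with no evidence of equal variances; a
pooled-variance Student option exists behind `pooled = TRUE`), computed
column-vectorised and verified against `stats::t.test`. Zero-variance
columns are reported with p = 1 and flagged, never dropped, so the
result length always equals the grid length. Multiplicity is controlled
by the Benjamini--Hochberg step-up rule at a target FDR of 1%
(implemented directly because the pipeline reports the realised raw-p
cutoff `p_(k)` and the rejection mask, which `p.adjust` does not
expose; `p.adjust(method = "BH")` is the cross-check in the tests).
The realised cutoff is data-dependent — the package reports the
mechanism and prints the cutoff as a percentage, it does not target any
particular published value. The report also carries the group
difference spectrum (cancer mean − control mean); `autoplot()` draws it
with the significant wavenumbers highlighted.

## PCA--LDA under leave-one-out cross-validation

`fit_pca()` is PCA of the centered, *unscaled* matrix (SNV has already
standardised each spectrum; column autoscaling would inflate noise
wavenumbers) computed via SVD for numerical stability, with n−1
eigenvalue conventions; `prcomp` serves as the oracle in tests, never
as the implementation. `fit_lda()` is the two-class Fisher
discriminant: `w ∝ Sw⁻¹(μ_cancer − μ_control)`, unit-normalised,
oriented so larger scores are more cancer-like; a singular within-class
scatter is ridged by `10⁻⁸ · mean(diag(Sw))`.

Decisions the underlying study description leaves open, resolved here
once:

* **Components fed to the LDA**: default `n_components = 19`, the
  component count at which such spectral PCAs typically report ≈99%
  cumulative variance, with an alternative `n_components = "variance"`
  mode retaining the smallest k reaching 99% per fold.
* **Priors and threshold**: equal priors, threshold at the midpoint of
  the projected class means (the 29/22 imbalance is mild); a
  prior-proportional threshold exists behind `priors =
  "proportional"`.
* **Ties** at the threshold classify as control — stated once,
  deterministic.
* **PCA inside each fold**: `loocv_pca_lda()` refits the PCA on the
  n−1 training samples of every fold (the stricter reading of training
  on all-but-one data point), so the held-out spectrum never influences
  its own projection; a no-leakage test verifies this. The cheaper
  alternative — one global PCA — would leak the held-out sample into
  the loadings.

Reported `score` values are centered on the fold's decision threshold,
so `score > 0 ⇔ predicted cancer`.

## Evaluation

`diagnostic_report()` computes the confusion matrix (cancer positive),
sensitivity, specificity and precision as percentages rounded **half
up** to one decimal (the convention of printed diagnostic tables; raw
fractions are kept alongside), and the AUC from the *LOOCV decision
scores* — not in-sample refit scores; the choice is recorded in the
report. The AUC is the Mann--Whitney concordance probability with ties
counted ½, computed from midranks and identical to the trapezoidal area
under the empirical ROC curve.

## Calibration and recovery studies

The test suite runs two simulation studies whose problem sizes were
fixed as the package's own design: 200 exchangeable-group cohorts
(all `cancer_multiplier = 1`; 51 samples × 5 replicates, full pipeline,
19 components) to verify that LOOCV accuracy and AUC center on
50%/0.5 within three Monte-Carlo standard errors and that BH at q = 1%
over 1001 wavenumbers rejects anything at all in no more than the
fraction of runs its guarantee allows; and one default-effect cohort to
verify the difference spectrum has the designed sign at all 20 bands,
that 2110 cm⁻¹ survives BH correction, and that LOOCV sensitivity and
specificity beat chance (binomial p < 0.01). `scripts/acceptance.R`
re-runs the same studies from scratch.

## Worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(generator_config(replicates_per_sample = 5, seed = 42))
mat <- cohort_matrix(cohort)

uni <- run_univariate(mat, target_fdr = 0.01)
glance(uni)

cv_full <- loocv_pca_lda(mat, n_components = 19)
cv_thio <- loocv_pca_lda(restrict_range(mat, 2000, 2200), n_components = 19)
diagnostic_report(cv_full, "full")
diagnostic_report(cv_thio, "2000-2200")
```

or, equivalently, `run_pipeline(generator_config(replicates_per_sample
= 5, seed = 42), n_components = 19)` for both windows plus provenance
in one call.

## Known limitations

* The generator's effect sizes are qualitative by construction; no
  published spectra exist in this package against which amplitudes
  could be estimated, so synthetic-cohort accuracies are properties of
  the generator settings, not of any real assay.
* Despiking and AsLS both degenerate on exactly noise-free input (see
  above); both stages are individually switchable.
* No Savitzky--Golay smoothing, derivative spectra, band-area fitting,
  permutation tests or alternative classifiers (PLS-DA, SVM) — outside
  the pipeline's scope.
* AUC confidence intervals are not computed.
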