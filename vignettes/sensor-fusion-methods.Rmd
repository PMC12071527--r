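---
title: "Methods: multi-sensor fusion for microbial spoilage prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-sensor fusion for microbial spoilage prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Culture-based enumeration of spoilage bacteria (total viable count, TVC, in
log~10~ CFU/g) takes days; spectral sensors give an answer in minutes. Three
modalities are modelled here: FTIR absorbance spectra over a wavenumber grid
(4000–400 cm^-1^), multispectral imaging (MSI) in 18 visible/NIR bands
(405–970 nm) and fluorescent multispectral imaging (MSIF) in 8 UV/blue bands
(270–405 nm), the imaging modalities tabularised as the per-band mean and
standard deviation of reflectance over the sample area (36 and 16 features).
Each modality sees biochemistry the others miss, which motivates fusing
them. This package implements the full comparison machinery: preprocessing,
PLS regression, three fusion architectures, two validation designs, and
paired statistical model comparison.

## Preprocessing

The default chain mirrors standard chemometric practice for these sensors:

* **SNV** (standard normal variate): each spectrum (row) is centred and
  scaled to unit standard deviation (n − 1 denominator). This removes the
  per-spectrum additive offset and multiplicative gain that path-length and
  scattering variation induce. SNV is idempotent and affine-invariant, and
  both properties are asserted exactly (1e-12) in the tests because the
  n − 1 convention is fixed.
* **Savitzky–Golay smoothing**, window 11 points, polynomial order 1,
  derivative order 0. Order 1 with an 11-point window is a gentle smoother
  that preserves band shapes at the spectral resolutions involved. Edges are
  handled by *antisymmetric* (point-symmetric) reflection padding: even
  reflection would bend a locally linear spectrum at the boundary, whereas
  point reflection continues it, so the filter reproduces straight lines
  exactly everywhere — a property the test suite checks literally.
* **Fingerprint restriction**: FTIR features are cut to the closed interval
  [900, 2000] cm^-1^, the "spoilage fingerprint" region dominated by
  polysaccharide, peptide and phosphate absorptions. On the default grid
  this retains exactly 1141 features. Restriction runs *after* smoothing so
  any residual edge effects fall outside the retained window.
* **z-score standardisation** (per feature) exists as an explicitly fitted
  transform: fit on training rows only, applied to test rows with the
  training statistics. It is used where the fusion design calls for it
  (early fusion) and nowhere implicitly.

SNV is applied to all three modalities and both meat types by default; the
original practice for some instrument/meat combinations is ambiguous, and
one uniform recipe keeps the pipeline honest and configurable (the recipe is
an ordered per-modality step list that can be overridden or expressed in
YAML).

SNV and Savitzky–Golay act on each row independently, so computing them
inside a resampling fold or on the pooled data is mathematically identical;
the drivers nevertheless apply them to the training and test partitions
separately, and the only *fitted* transforms (standardisers, PLS models) are
fit on fold-training rows exclusively. A dedicated test perturbs test rows
and asserts, by serialised-object equality, that no fitted training-side
statistic changes.

## PLS1 by NIPALS, centering only

The base learner is single-response partial least squares regression. PLS1
needs no iterative inner loop: per component the weight vector is
closed-form (w ∝ X^T^y), followed by scores t = Xw, loadings p = X^T^t/t^T^t
and q = y^T^t/t^T^t, and deflation of X. The coefficient vector
b = W(P^T^W)^-1^q turns prediction into one affine map, and the rotation
W(P^T^W)^-1^ projects new data into the latent space.

Inputs are mean-centred but **not** variance-scaled inside PLS: SNV has
already normalised the spectra row-wise, and the one place the analysis
wants per-feature scaling (early fusion, where blocks of very different
dimensionality and units are concatenated) applies an explicit z-score
standardiser. This choice changes numbers relative to an auto-scaling PLS
implementation and is therefore stated prominently; it is validated by a
property suite (equality with ordinary least squares at full rank, score
orthogonality, permutation invariance, monotone training fit) and by
agreement with an independent reference implementation (mixOmics) to 1e-6,
used strictly as a test oracle.

Rank exhaustion (‖X^T^y‖ below 1e-12 of its initial value) truncates the
model with a warning rather than an error, so tuning over generous LV
ranges cannot crash on low-rank folds; ties in cross-validated RMSE are
broken toward fewer total latent variables, then lexicographic order, making
selection deterministic.

## Fusion architectures

* **Early**: each block is z-scored (train-fitted), blocks are concatenated
  horizontally, and one PLS model is fit. Simple, but concatenation lets a
  high-dimensional block dominate.
* **Mid (feature-level)**: one PLS model per modality (its own LV count),
  training scores concatenated (width = sum of base LVs), and a second PLS
  model with u latent variables fit on that matrix. Base models are fit on
  the full training partition before score extraction — the score spaces
  are reused from the single-sensor models, with no out-of-fold scheme at
  this level.
* **Late (decision-level)**: stacked generalisation. Training rows are
  shuffled once (seeded) into 20 folds; for each fold, base models fit on
  the complement predict the held-out rows, giving one out-of-fold (OOF)
  prediction per row per modality; ordinary least squares with intercept
  and unconstrained (possibly negative) weights regresses y on the OOF
  matrix; base models are then refit on all training rows for inference.
  Only the OOF variant is implemented — training the meta-learner on
  in-sample base predictions is the failure mode stacking exists to avoid.
  Perfectly collinear OOF columns receive weight 0 rather than NA.

The modality order is fixed as (MSI, FTIR, MSIF) for reproducible column
layouts; PLS itself is invariant to column order, and a test confirms
predictions do not depend on it.

## Validation designs

**Batch-on-batch**: train and tune on sourcing batch 1, test on batch 2 — a
robustness probe against batch effects. Tuning uses 3 × 10-fold repeated
cross-validated RMSE (RMSEcv). Every condition present in the data yields
its own batch-2 test set, so a model trained on one packaging condition is
also scored on the other (cross-condition robustness).

**Repeated nested cross-validation**: 10 repeats × 5 outer folds (50
assessments per model). Per repeat the rows are shuffled with a
repeat-derived seed (`seed + repeat`, so adding repeats never changes
earlier splits) and split into 5 outer folds; per outer fold, each model is
tuned by 5-fold RMSEcv on the remaining data, refit with the selected
hyperparameters, and scored on the held-out fold. Every model sees the
identical series of outer splits, which is what makes fold-level RMSEs
pairable across models.

Default LV search ranges are MSI 2–17, FTIR 2–20, MSIF 2–7, early fusion
2–20 and the mid-fusion meta layer 2–17; the larger fusion grids use seeded
uniform random search *without replacement* (distinct candidates), with
1500/2500/400 iterations for two-block mid, three-block mid and late fusion
respectively. All ranges and iteration counts are config-overridable.

## Paired model comparison

Fold-level RMSEs of two models under matched splits form paired samples.
The Wilcoxon signed-rank test drops zero differences (the classical
treatment; recorded because Pratt's method is a defensible alternative),
ranks |d| with midranks for ties, and uses W = min(W⁺, W⁻). For n ≤ 25 the
two-sided p-value is exact, computed from the tie-aware null distribution of
W⁺ over all 2^n^ sign assignments (by convolution; verified against brute
force enumeration in the tests); beyond that, a normal approximation with
continuity correction and tie-corrected variance. Families of pairwise tests
are Holm–Bonferroni adjusted (delegating to `stats::p.adjust`); the family
is all pairs within one comparison panel by default, and configurable,
since a global-versus-per-panel family choice is a judgement call.
Significance tiers `*`/`**`/`***` at adjusted p < 0.05/0.01/0.001, with an
annotation when a significant difference favours a non-fusion model.

## The synthetic-data generator

No public spectral dataset accompanies this problem setting, so the
generator produces datasets with the statistical structure the analysis
assumes — it is first-class, tested code, not a fixture.

**Growth**: TVC follows a three-phase curve in log-count space — flat at the
initial load until the lag time, then a shifted symmetric logistic
y(t) = y₀ + (y~max~ − y₀)·tanh(r·(t − lag)/2) rising to a plateau. The rate
r = rate_at_ref · exp(temp_sensitivity · T) · condition_rate_factor grows
exponentially with temperature (reference 0 °C) and is slowed by protective
packaging. Defaults (y₀ = 5.2, y~max~ = 9 log CFU/g, rate 0.02 h^-1^,
sensitivity 0.1 °C^-1^, lag 12 h, vacuum factor 0.55) put initial loads in
the 4.5–6 log CFU/g range and carry all conditions past the 7–8 log CFU/g
spoilage threshold within the sampling horizon, with the 10 °C "abuse"
condition growing fastest — the qualitative shape such storage trials
report. Replicate noise is Gaussian (sd 0.25 log CFU/g) and batch 2 is
shifted by +0.7 log CFU/g, inside the ~0.5–1 log batch separation such
trials show, plus a small (3 %) spectral gain shift.

**Spectra**: each block is `baseline + z·L + s·S`, row-scaled by a
multiplicative gain (sd 8 %) and additive offset (sd 4 %) — exactly the
artifact family SNV removes — plus i.i.d. measurement noise. The TVC
loading L concentrates in 1750–1400 cm^-1^ for FTIR (amide-region Gaussian
bumps) and 450–700 nm for MSI; s is a shared nuisance factor common to all
modalities. The key lever is z = tvc + unique_sd·u with u drawn
*independently per modality*: modality-unique interference enters along the
same spectral direction as the signal, so each single sensor has an
irreducible error floor (≈ its unique_sd) while fusion can average
independent interference away. Defaults (FTIR 0.40, MSI 0.35, MSIF 0.60
log-CFU-equivalent) encode plausible relative reliabilities — MSI most
reliable, MSIF least — and were chosen once as study conditions. With all
noise, artifact and interference terms set to zero the spectra are exactly
affine in TVC, which the tests exploit as a closed-form check, and a
ground-truth export (`oracle_signal_report`) returns the exact generative
loadings for recovery tests.

The FTIR grid is anchored so that the closed interval [900, 2000] cm^-1^
contains exactly 1141 uniformly spaced points (step 1100/1140 ≈ 0.965
cm^-1^ — the instrument's sampling step is not published, so the retained
feature count is adopted as the defining constraint), extended over
4000–400 cm^-1^; a thinning factor that divides 1140 keeps both endpoints
on the grid for reduced-scale work.

**What it does not emulate**: instrument physics, scattering nonlinearity,
wavelength-dependent noise, species-level microbiota succession,
image-segmentation variability, or real covariance between modalities
beyond the shared factor. Passing tests therefore demonstrate that the
*pipeline machinery* is correct and that fusion recovers gains where
modality-unique information exists by construction — not that any particular
instrument combination will show those gains on real meat.

## Problem sizes and numerical choices

The packaged fusion-recovery experiment (`fusion_recovery_experiment`) runs
ten seeded replicate studies of ~100–150 samples (one aerobic scenario,
three temperatures, two batches, 10×-thinned FTIR grid) through 2 × 5-fold
nested CV over reduced LV grids with 10 OOF folds — sizes chosen so the
whole experiment completes in a couple of minutes on one CPU while leaving
the fusion-vs-single-sensor contrast far larger than its fold-to-fold
variability. Mid and late fusion beat the best single sensor in 10 of 10
runs at these settings; the committed property is ≥ 8 of 10.

Other conventions: the accuracy metric counts |error| ≤ 1 log CFU/g
inclusively and is reported as a percentage in summaries while staying a
fraction internally; R² uses the test-set definition 1 − SS~res~/SS~tot~
and may be negative; CSV serialisation uses 17 significant digits and the
loader parses through `strtod`, so matrices round-trip bit-exactly (the
FTIR wavenumber axis is carried in column names at 4 decimal places);
derived seeds stay inside the 32-bit integer range.

## Known limitations

Single-response PLS only (no PLS2/SIMPLS/kernel variants), no
variable-selection wrappers, no LOOCV mode, no Pratt zero-handling, no
omnibus (Friedman) test, and no vendor binary format support. The synthetic
generator's linear-Gaussian structure is deliberately simple; conclusions
about real instruments require real spectra.
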