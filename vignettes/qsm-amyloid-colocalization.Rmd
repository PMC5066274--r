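---
title: "Iron-amyloid colocalization from multi-modal 7T imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iron-amyloid colocalization from multi-modal 7T imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Brain iron accumulates in several neurodegenerative conditions and can be
mapped in vivo because iron-rich tissue perturbs the local magnetic field:
quantitative susceptibility mapping (QSM) inverts the measured gradient-echo
phase into a map of tissue magnetic susceptibility (chi, in parts per
billion), which in cerebral gray matter tracks iron concentration. Amyloid
plaque load, the other canonical marker of Alzheimer-type pathology, is
measured with PiB-PET as a standardized uptake value ratio (SUVR) normalized
to cerebellar gray. This package implements, end to end, an analysis that
asks whether the two pathologies colocalize in elderly subjects at risk for
Alzheimer's disease: cognitively normal controls versus subjects with mild
cognitive impairment (MCI), stratified by APOE-e4 carrier status. The
pipeline (i) reconstructs referenced susceptibility maps from wrapped
multi-echo 7T phase, (ii) quantifies amyloid load as cerebellum-anchored
SUVR with a cortical composite score, (iii) derives a group-level mask of
voxels whose resting-state coupling to a medial-prefrontal-cortex (MPFC)
seed is elevated when MCI coincides with high iron, and (iv) correlates
mask-mean susceptibility with mask-mean SUVR across MCI subjects, with
APOE-e4-stratified comparisons and odds ratios.

Because no subject-level images are publicly available for such a cohort,
the package ships a fully synthetic multi-modal generator with the
statistical structure the analysis assumes, so that every stage is testable
at desk scale against known ground truth.

# The synthetic cohort

`cohort_spec()` fixes the study conditions: 22 controls and 15 MCI subjects
(7 and 6 APOE-e4 carriers, 8F/14M and 5F/10M, assigned at exactly those
counts with the assignment permuted by seed), ages drawn from N(72, 5) and
N(75, 8) truncated to [62, 89] years. Per structure and per (group x APOE)
cell, subject-level regional means of chi and SUVR are drawn from
Normal(cell mean, STE x sqrt(n_cell)) using the cell parameters in
`cell_parameters()`; the STE-to-SD conversion uses the cell sizes 15/7/9/6.
Within the frontomedial colocalization region (frontal lobe plus MPFC
patch) each subject's chi and SUVR deviations share a Gaussian copula whose
Pearson parameter is `2 sin(pi rho_s / 6)`, so the population Spearman
correlation equals the requested rank coupling `rho_s` exactly in the
bivariate-normal limit. The default coupling is 0.86 for MCI; for controls,
where no value is established, we chose 0.3 once - weak but nonzero
coupling, consistent with colocalization being a risk-state phenomenon.

Anatomy is a deterministic geometric phantom (`make_phantom_labels()`):
paired ellipsoidal nuclei, a cortical shell split into four lobes, central
ventricular CSF, a cerebellar patch, an MPFC seed patch, and white-matter
filler inside an ellipsoidal head, all defined in normalized coordinates so
the same geometry scales from the 16^3 smoke grid to the 64^3 default.
Anatomy is identical across subjects, which stands in for perfectly
co-registered data (spatial registration is out of scope). White matter is
assigned a small negative susceptibility (-20 ppb, isotropic), reflecting
myelin's weak diamagnetism; ventricular CSF is generated at offset 0 with
the smallest between-subject variability of any candidate region, so the
data-driven reference-selection rule has a well-defined correct answer.

The forward model produces what a scanner would see: the frequency-shift
field is the k-space product of chi with the unit dipole kernel
`D(k) = 1/3 - kz^2/|k|^2` (D(0) = 0), scaled by the 7T Larmor frequency;
each echo's complex signal has unit magnitude inside the head plus circular
Gaussian noise at SNR 50, and the stored phase is the wrapped principal
argument at TE = 6/12/18 ms. BOLD series live on a 4x coarser grid
(mirroring the coarser fMRI resolution of the protocol): the MPFC seed
carries a band-limited (0.01-0.1 Hz) latent signal, frontomedial target
voxels add `alpha x latent` with `alpha` calibrated per (group x iron) cell
so the true seed-target correlation is 0.6 for MCI-and-high-iron and
0.10-0.15 elsewhere, and six synthetic motion regressors plus CSF/WM means
(with a motion component mixed into every voxel) populate the confound
model. What the generator does *not* emulate: realistic anatomy, scanner
artifacts (motion, distortion, coil sensitivity), PET kinetics,
partial-volume effects, or registration error - so green tests demonstrate
algorithmic correctness under the stated statistical model, not robustness
to those real-data effects.

# QSM reconstruction

The per-subject chain (`qsm_reconstruct()`) uses the 12 and 18 ms echoes
and follows the protocol order: Laplacian unwrapping, brain masking,
phase-to-frequency conversion, V-SHARP background removal per echo, echo
averaging, LSQR dipole inversion. Referencing is cohort-level: among
candidate reference regions (white matter, ventricular CSF) the one with
the lowest across-subject standard deviation of region-mean chi is chosen,
and its mean is subtracted from every map.

Numerical choices worth recording:

* **Unwrapping.** The Poisson problem
  `Lap(phi) = cos(phi_w) Lap(sin phi_w) - sin(phi_w) Lap(cos phi_w)` is
  solved spectrally on the even-symmetric (mirror) extension of the volume
  rather than with zero padding: a mirror extension keeps non-periodic
  fields continuous, which matters for the linear-ramp case where zero
  padding corrupts the Laplacian at the volume boundary. The smooth
  estimate is then snapped back to the measured phase modulo 2 pi
  (congruence restoration), removing the harmonic boundary residual
  wherever it is below pi.
* **Brain mask.** A self-contained stand-in for BET: fractional threshold
  (0.3) of the robust maximum, largest 6-connected component, hole filling.
* **V-SHARP.** Integer kernel radii from ceiling(4 mm / voxel) down to 1
  voxel; each voxel keeps the estimate from the largest sphere that fits
  inside the mask; validity is where at least the 1-voxel sphere fits. The
  spherical-mean filtering is undone by k-space deconvolution with
  `(delta - rho_max)`. The protocol's "regularization parameter 0.05" is
  interpreted as the truncation threshold of this inverse filter; inside
  the ill-conditioned band we cap the inverse gain at 1/0.05 rather than
  zeroing it, which preserves part of the low-frequency field at identical
  background suppression.
* **Dipole inversion.** Plain masked least squares solved with
  Paige-Saunders LSQR (zero start, tolerance 1e-6, at most 300 iterations,
  stopping on either the residual or the least-squares optimality
  criterion). The susceptibility support is restricted to the brain mask:
  with sources allowed outside the observed region, the converged
  minimum-norm solution places ghost sources there and systematically
  underestimates interior contrast; with support restriction the inversion
  of an unfiltered field is exact to well below 1 ppb on the phantom. No
  additional regularizer is used.
* **Ties and degenerate inputs.** Reference-region ties break to the first
  candidate in sorted order (logged); empty eroded ROIs are dropped with a
  warning; LSQR non-convergence returns the partial result flagged.

## A documented limitation: SHARP and the field's head-scale band

The spherical-mean-value filter annihilates not only background fields but
also the components of the *internal* field whose spatial scale exceeds the
kernel: in k-space, everything where `|1 - FT(rho_max)|` is below the
truncation threshold is observed only through a strongly attenuated gain.
On a 64-voxel phantom with a 4 mm kernel this band covers the head-envelope
scale, where the basal-ganglia cluster and the white-matter compartment
have substantial field content. The test suite measures the consequence
directly: reconstruction from the true (unfiltered) field recovers every
structure mean to sub-ppb accuracy, while the full chain - any consistent
variant of filtering plus restoration we evaluated, including truncated and
capped deconvolution and joint single-operator fitting - underestimates
deep-nuclei means by roughly 10-20 percent. This is a property of
spherical-mean background removal at this mask-to-kernel geometry, not of
the solver; the corresponding round-trip check in `test-acceptance.R`
asserts the strict tolerance and is expected to fail for the deep nuclei,
serving as a regression record of the effect. Structures whose scale is
small against the kernel (thalamus in our geometry, CSF, accumbens) are
recovered within tolerance.

# Connectivity and group mask

Per subject, confound regression (intercept + 6 motion + CSF + WM) runs
first, then the zero-phase frequency-domain band-pass (0.01-0.1 Hz,
brick-wall, DC removed) - a fixed documented order. The seed signal is the
unweighted mean over MPFC voxels; voxelwise Pearson correlations are
Fisher-z transformed with |r| clamped at 1 - 1e-7. The group model is a
2x2 cell-means fit (MCI x iron class, iron from the cohort-wide median
split of cortical gray susceptibility), and the tested effect is the
one-sided contrast "MCI-and-high-iron cell exceeds the mean of the other
three cells", our reading of a combined MCI-and-iron effect; with fewer
than 2 subjects in any cell the model falls back to (MCI and high-iron)
versus rest, recorded in the result. Benjamini-Hochberg correction runs
across all analysis voxels and the mask keeps q < 0.001. Seed voxels are
excluded from the group test.

# ROI statistics and colocalization

ROI means use 2-voxel (6-connected) erosion against partial-volume and
edge effects; volumes are voxel counts times voxel volume, with the
intracranial-volume correction `volume x (group mean ICV / subject ICV)`.
Group comparisons are per-structure ANCOVAs (`value ~ group + age +
gender`) - the univariate reading of a one-way MANCOVA, since per-structure
p-values and effect sizes are what the tabular outputs report - followed by
Benjamini-Hochberg across structures (level 0.05 for tables; the voxelwise
mask uses 0.001). Cohen's d is computed on raw, not covariate-adjusted,
values; this is a recorded, switchable choice. Median splits use the
mid-value threshold with ties going "low"; for 37 distinct values this
yields 18 high and 19 low. Odds ratios apply the Haldane-Anscombe +0.5
correction when any cell is zero, with Wald log-scale 95% intervals and
Fisher's exact p. The Spearman statistic is the Pearson correlation of
mid-ranks; its p-value is exact (permutation distribution) for n <= 10
without ties and t-approximate otherwise; adjusted R^2 comes from the OLS
fit of SUVR on chi. The colocalization correlation is computed over MCI
subjects only, while the "high/low" classifications reuse cohort-wide
median thresholds. The cortical composite is the voxel-weighted mean over
the union of the four lobes ("merged" read as pooled voxels, not a mean of
ROI means). "Gray matter" in mask extraction means the atlas labels, not a
subject-specific segmentation.

# Problem sizes and determinism

Default analyses run on a 64^3 phantom (1 mm voxels) with BOLD at 16^3 x
210 frames; the test suite uses 16^3-48^3 grids for unit properties, the
64^3 phantom for the round trip, 10 seeds for mask recovery, 2000 subjects
for copula calibration, and 1000 replicates for FDR and type-I
calibration - sizes chosen so the full suite runs on a laptop. Every
stochastic stage takes an explicit seed, restores the caller's RNG state,
and derives per-subject substreams; reports contain no timestamps, so a
rerun with the same seed is byte-identical (this is itself a test).
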