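---
title: "Quantitative susceptibility mapping of the dentate nuclei: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative susceptibility mapping of the dentate nuclei: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`dentateqsm` implements a complete desk-scale analysis of iron-sensitive MRI
of the cerebellar dentate nuclei: simulation of multi-echo gradient-echo
(GRE) acquisitions of a susceptibility phantom, reconstruction of
quantitative susceptibility maps (QSM), construction of dentate
volumes-of-interest (VOIs) from traced silhouettes, and the group-level and
voxel-level statistics used in dentate morphometry studies of cerebellar
ataxia.  Because clinical MRI data of this kind are not publicly
deposited, every stage is exercised against a synthetic cohort whose
physics (the dipole field model) and structure (group effects, covariates)
are generated by the package itself — the generator is first-class, tested
code, and all quantitative claims in the test suite are claims about this
synthetic system, not about any clinical dataset.

# The forward model

A tissue susceptibility distribution $\chi(\mathbf r)$ (expressed in parts
per billion, ppb) perturbs the Larmor frequency according to the k-space
dipole relation

$$\Delta f(\mathbf k) = f_0 \, D(\mathbf k)\, \chi(\mathbf k), \qquad
D(\mathbf k) = \tfrac13 - \frac{(\mathbf k\cdot\hat b_0)^2}{|\mathbf k|^2},$$

with $f_0 = 127.728$ MHz at 3 T (42.576 MHz/T; stated once in `qsm_f0()`)
and $D(0) := 0$, which removes the undefined k = 0 term and fixes the
arbitrary global offset — susceptibility maps are therefore always
*referenced*, here to the mean over brain tissue.  The complex GRE signal
at echo time $TE$ is

$$S(TE) = S_0\, e^{-R_2^* TE}\, e^{i(\phi_0 + 2\pi\,\Delta f\, TE)} + \varepsilon,$$

with i.i.d. complex Gaussian noise per channel (a single-coil model;
multi-coil combination is out of scope).  Phase is stored wrapped to
$(-\pi, \pi]$, half-open at $-\pi$.  The default echo times are the
four-echo protocol 6.47/17.23/27.99/38.75 ms at 0.5 mm isotropic voxels.

# The dentate phantom

The dentate nucleus is a thin, corrugated, high-susceptibility shell
("sac") of gray matter enclosing lower-susceptibility white matter.  No
quantitative parametric geometry of the nucleus is published, so the
phantom geometry is an explicit synthetic choice: each hemisphere is an
open-topped ellipsoidal shell whose radius is sinusoidally modulated
(six corrugation lobes, 0.3 mm amplitude), mirrored about the mid-sagittal
plane, embedded in a spherical "brain" of 15 mm radius on an $80^3$ grid of
0.5 mm voxels.  Key scales:

* wall susceptibility 100 ppb over tissue, interior white matter 40 ppb —
  the resulting bulk means (tens of ppb relative to brain) match the
  magnitudes reported for dentate QSM;
* wall thickness 1 mm; shell semi-axes 3.8/3.2/2.8 mm (a scaled-down
  dentate: the desk-scale grid cannot hold a full head);
* a CSF pocket (R2* = 4 s$^{-1}$, $\chi = 0$) inside each sac exercises
  the CSF-exclusion rule;
* compartment R2*: tissue 20, wall 35, interior 28 s$^{-1}$;
* background fields that are *harmonic inside the brain mask by
  construction*: a harmonic polynomial of order ≤ 2 (basis $x, y, z, xy,
  xz, yz, x^2\!-\!y^2, 2z^2\!-\!x^2\!-\!y^2$) plus external point-dipole
  sources placed outside the mask — exactly the class of fields that SHARP
  is designed to remove;
* complex noise $\sigma = S_0/40$ (SNR 40) by default.

Two geometry constraints matter and were found the hard way: the shells
must be separated by several voxels at the midline (otherwise they merge
into one 26-connected component and hemisphere splitting and per-hemisphere
hulls are meaningless), and the dentate must sit at least the largest SMV
kernel radius (10 voxels) inside the brain mask, as it does in a real
whole-brain mask — with a tighter margin the large kernels never fit near
the nuclei and the background-removal step destroys the dentate field.

The ground-truth bulk mask is defined as the filled sac (boundary
inclusive), eroded once with the 3×3×3 box and with the CSF pocket
removed — i.e. by the same morphological definition the analysis pipeline
uses, so the Dice overlap measured between the automatic DN-bulk and the
truth compares like with like.

## The synthetic cohort

`cohort_spec()` encodes a two-group study: 16 patients vs 16 matched
controls by default, ages uniform over 31.6–68.3 years, TIV (total
intracranial volume) normal with mean 1546, sd 135 cm³.  Group effects are
parameterized at magnitudes reported for SCA1 (spinocerebellar ataxia
type 1) cohorts in dentate iron imaging: a dentate susceptibility shift of +39 ppb in patients
(applied uniformly to wall and interior, so the expected patient−control
difference of true bulk mean $\chi$ equals the parameter exactly), and a
dentate volume factor of 0.78.  A linear volume–TIV relationship
(0.15 mm³/cm³) and per-subject dispersions (30 ppb susceptibility,
25 mm³ volume) are synthetic choices on the scale of reported
between-subject standard deviations.  SARA (ataxia severity, 0–40) is
generated for patients from an affine model in volume, susceptibility and
age with Gaussian noise, clipped to range; controls receive near-zero
scores.  What the generator does **not** emulate: acquisition artefacts
(parallel-imaging aliasing, partial Fourier, motion, flow), multi-coil
phase combination, spatial normalization error, and manual-tracing
variability — passing tests therefore validate the analysis contracts, not
robustness to those effects.

# Reconstruction

The chain in `reconstruct_qsm()`:

1. **Denoising** (optional, off by default): a 3×3×3 median filter on the
   real and imaginary channels, `strength` = number of passes.  Chosen as a
   documented edge-preserving filter with an off switch; it is not on the
   quantitative path.
2. **Unwrapping**: quality-guided ("best path") region growing, quality =
   negated sum of squared wrapped second differences, 6-connected growth,
   ties broken by linear voxel index for determinism; each connected mask
   component has its own global $2\pi k$.
3. **Frequency**: per echo $f_i = \phi_i/(2\pi\,TE_i)$; combination by the
   SNR-optimal weights $w_i \propto (|S_i|\,TE_i)^2$, after a temporal
   pass that snaps each echo's phase to the multiple of $2\pi$ best
   matching the prediction from earlier echoes.
4. **Background removal**: multi-radius SMV (SHARP) with kernel radii
   1–10 voxels; at each voxel the largest kernel that fits inside the
   brain mask is applied ($\delta-\rho_r$), and the result is deconvolved
   by the largest-radius kernel with k-space truncation where
   $|1-P_R(\mathbf k)| < 0.01$.  Kernels are rasterized
   voxel-center-inside-radius and normalized to sum 1; FFT convolution
   with periodic wrap is acceptable because the phantom guarantees
   padding of at least the largest radius.  The *reliability mask* is the
   erosion by the smallest radius.  Re-running SHARP on its own output
   changes the tissue field by about 1% RMS deep inside the mask and a
   few percent near the boundary bands; the deconvolution is global, so
   support-edge effects delocalize — per-band deconvolution was evaluated
   and is dramatically worse (small kernels are ill-conditioned).
5. **Inversion**: two regularized inverses of $D$ are provided — TKD
   (threshold 0.2: $D$ values inside the cone replaced by
   $\mathrm{sign}(D)\cdot t$) and Tikhonov ($D/(D^2+\lambda)$).  Both
   attenuate the source spectrum near the dipole cone and bias VOI means
   low; the standard remedy, on by default, rescales the map by the
   central value of the inversion's point-spread function (the k-space
   mean of $D \cdot D^{-1}_{\mathrm{reg}}$).  The *package default* is
   Tikhonov with $\lambda = 10^{-3}$: measured on the default phantom,
   the bulk-VOI mean is recovered within ~2% both noiseless and at
   SNR 40, whereas TKD at its conventional threshold 0.2 is ~15–18% low
   uncorrected and ~8% high after the global PSF correction (the
   correction factor is exact only for sources whose spectrum matches the
   k-space average).  $\lambda = 10^{-3}$ attenuates only $|D| < 0.03$,
   a weak regularization appropriate for the SNR of multi-echo GRE; it
   was fixed once from this reasoning, with TKD retained as the
   config-exposed alternative.
6. **Referencing**: subtraction of the mean over the reliability (brain
   tissue) mask; exact zero mean, idempotent.

**R2\*** is fit per voxel by weighted least squares of $\log|S|$ on TE
with weights $|S|^2$; negative slopes are clipped to zero and flagged, and
voxels with any zero magnitude are NaN.

# Dentate VOIs

DN-sil (the traced silhouette; in the pipeline, the phantom's true shell
plays the role of the manual tracing) is split into hemispheres by
26-connected components and the mid-sagittal plane of the brain mask;
straddling components go to the majority side with a warning.  DN-bulk is
built per hemisphere as: convex hull of the silhouette voxel centers
(a hand-written incremental 3D hull returning half-space facets; no hull
library is available in the environment and the rasterization rule is a
contract of this package), rasterized boundary-inclusive at voxel
centers, eroded once with the full 27-neighbour box (out-of-grid counts
as background), then voxels with $R_2^* < 15\ \mathrm{s}^{-1}$ removed
(CSF exclusion).  Erode-then-filter order follows the description's
sentence order; the rasterization rule (voxel-center, boundary counts as
inside) is a documented choice.  An externally edited mask can override
the automatic result, mirroring manual correction.

Metrics: volume = voxel count × voxel volume summed over hemispheres;
mean $\chi$ over all VOI voxels; susceptibility mass
$\chi_{mass} = (\text{volume}/1000)\cdot\bar\chi$ in ppb·cm³, an identity
the package maintains exactly.

# Statistics

* **Head-size correction**: volumes are regressed on TIV *in controls
  only* (the "normal" relationship); residuals for all subjects are
  standardized by the whole-sample residual sd (sample sd, $n-1$ — the
  $n$ vs $n-1$ choice is immaterial after standardization-based tests but
  is documented here as sample sd).
* **ANCOVA**: `dep ~ group + age` (+ optional covariates), type-III
  (marginal) F per term via model comparison; partial
  $\eta^2 = SS_{term}/(SS_{term}+SS_{error})$.  Welch t-tests for
  demographics (pooled vs Welch unspecified in the source protocol; Welch
  is the safer default).  Sidak post hoc:
  $p_{adj} = 1-(1-p)^m$.
* **Correlation with severity**: "Spearman with age as covariate" is read
  as the standard partial correlation on ranks: rank-transform all three
  variables, partial Pearson of the ranks given the covariate ranks,
  p from the t approximation on $n-3$ df.
* **Reliability**: ICC(3,1), the consistency form of the two-way
  mixed-effects single-rater model, from the two-way ANOVA mean squares;
  the absolute-agreement variant is a flag.
* **Voxelwise inference**: per-voxel GLM with age covariate, TFCE
  ($E = 0.5$, $H = 2$, 26-connectivity, $dh = \max|t|/100$ — tool-default
  exponents, config-exposed), and FWE control by the permutation null of
  the maximum TFCE statistic.  Covariates are handled by Freedman–Lane
  residual permutation (the standard scheme of the named tool); for score
  correlations the score is residualized against age and the residuals
  permuted.  Positive and negative contrasts are tested separately, each
  at $\alpha = 0.05$, with no additional two-sidedness correction —
  mirroring the red/blue one-sided maps of the source analyses; the FWE
  calibration test therefore checks the per-contrast rate.  Corrected p
  never falls below $1/(n_{perm}+1)$.

# Numerical choices and scales

* FFTs use standard frequency ordering; anisotropic voxels enter through
  per-axis k-spacing.  All fields are Hz, TEs seconds, $\chi$ ppb at API
  boundaries.
* The hull uses a degeneracy tolerance of $10^{-9}$ and a boundary
  tolerance of $10^{-7}$ of the point-cloud scale; coplanar hemispheres
  raise an error naming the hemisphere.
* TFCE is computed by a descending-threshold union-find with lazily
  accumulated per-cluster increments — exactly the Riemann sum
  $\sum_h e(h)^E h^H\,dh$, only faster than per-threshold relabeling.
* Problem sizes in the tests: dipole physics and SHARP on $64^3$ grids;
  the end-to-end phantom at its default $80^3$; statistical calibrations
  at the study's group size ($n = 16$/group; 2000 null ANCOVA
  simulations; 200 null datasets × 200 permutations on $16^3$ grids for
  the FWE rate).  The demo pipeline configuration runs 6 + 6 subjects on
  a $56^3$ grid so a full run stays interactive.

# Known limitations

* TKD at threshold 0.2 is provided for fidelity to common practice but
  under-recovers extended-VOI means even after global PSF correction;
  quantitative work should use the default corrected Tikhonov inversion
  (or compare both).
* SHARP's re-application stability is ~1% RMS only in the deep region
  where the largest kernel fits; boundary bands are less self-consistent.
* The hemisphere split assumes the mid-sagittal plane of the brain mask
  separates the nuclei; pathologies that merge the silhouettes across the
  midline would need the manual override.
* The cohort generator draws geometry by scaling shell radii; the eroded
  bulk volume therefore scales slightly faster than the nominal volume
  factor (erosion removes a fixed-width layer), which is physically
  sensible but means `volume_scale` is exact for the sac geometry, not
  for the post-erosion bulk.
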