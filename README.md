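# dentateqsm

Quantitative susceptibility mapping (QSM) and morphometry of the cerebellar
dentate nuclei, as a reusable, fully tested R pipeline.

The dentate nucleus is the largest cerebellar nucleus and is physiologically
iron-rich, which makes it bright on susceptibility maps computed from
multi-echo gradient-echo (GRE) phase. Studies of cerebellar ataxia compare
dentate volume, mean susceptibility χ (a proxy for iron concentration) and
*susceptibility mass* χ_mass = volume × mean χ (a proxy for total iron
content) between patients and matched controls. This package implements
that entire analysis for researchers who want to develop, validate or teach
it without access to clinical data:

* **Simulation** — a digital dentate phantom (thin corrugated
  high-susceptibility shells, white matter inside the sac, CSF pocket,
  harmonic background fields, compartment R2\*) passed through the forward
  dipole model `Δf = f₀·IFFT(D(k)·FFT(χ))`, `D(k) = 1/3 − k_z²/|k|²`, to
  complex multi-echo GRE data with wrapped phase and complex Gaussian
  noise; plus a two-group cohort generator with controllable effects
  (χ shift, volume factor, volume–TIV slope, SARA severity model).
* **Reconstruction** — 3D quality-guided phase unwrapping, per-echo
  frequency scaling `φ/(2π·TE)` and SNR-optimal multi-echo combination,
  multi-radius SHARP background-field removal (spherical kernels of 1–10
  voxels, high-pass 0.01), regularized dipole inversion (PSF-corrected
  Tikhonov by default; TKD at threshold 0.2 available), referencing to
  mean brain tissue, and log-linear R2\* mapping.
* **Dentate VOIs** — DN_bulk built from the traced silhouette (DN_sil) by
  per-hemisphere convex hull, rasterization, one 3×3×3 erosion and
  exclusion of voxels with R2\* < 15 s⁻¹ (CSF); volumes, mean χ and χ_mass
  per hemisphere and summed.
* **Statistics** — TIV residualization fit on controls and standardized
  over the whole sample; ANCOVA (group + age) with partial η²;
  Sidak-adjusted post hocs; age-controlled partial Spearman correlations
  with SARA; two-way mixed-effects ICC; and voxelwise permutation tests
  with threshold-free cluster enhancement (TFCE) and family-wise error
  control (Freedman–Lane, max-statistic null).

## Worked example

```r
library(dentateqsm)
spec  <- phantom_spec()                 # 80^3 grid, 0.5 mm voxels
truth <- make_dentate_phantom(spec)
echoes <- simulate_acquisition(truth)   # four echoes, SNR 40
rec  <- reconstruct_qsm(echoes, truth$brain_mask)
sil  <- split_hemispheres(truth$dn_sil, truth$brain_mask, 0.5)
bulk <- build_dn_bulk(sil, rec$r2star, r2star_min = 15)
voi_metrics(rec$chi_ppb, bulk)
```

which prints (abbreviated):

```
Dentate ground-truth phantom: 80x80x80 grid, 0.5 mm voxels
  DN_sil 1716 voxels, DN_bulk 1418 voxels, brain 113104 voxels
DN_bulk mask: 735 left / 735 right voxels (0.5 mm voxels)
DN_bulk: volume 183.8 mm^3, mean chi 48.1 ppb, mass 8.83 ppb cm^3
true referenced bulk mean: 47.2 ppb (recovery error +1.8%)
```

The reconstructed bulk mean susceptibility (48.1 ppb relative to mean brain
tissue) recovers the phantom's true referenced value (47.2 ppb) to within a
few percent at SNR 40; volume and mass follow the identity
χ_mass = (volume/1000)·χ̄ exactly.

The full pipeline — cohort simulation, per-subject reconstruction, VOI
metrics, group statistics and voxelwise permutation testing — runs from a
single YAML configuration:

```r
cfg <- validate_config()     # demo scale: 6 + 6 subjects, 56^3 grid
run_pipeline(cfg)            # writes NIfTI maps, TSV tables, JSON reports
```

or from the shell via `inst/cli/dentateqsm run --config cfg.yaml`.

## Package layout

| Area | Files |
|---|---|
| Forward model & phantom | `R/forward.R`, `R/phantom.R`, `R/cohort.R` |
| Reconstruction | `R/recon.R`, `R/sharp.R` |
| Dentate VOIs | `R/voi.R` (+ `src/hull.cpp`) |
| Group statistics | `R/groupstats.R` |
| Voxelwise statistics | `R/voxelwise.R` (+ `src/tfce.cpp`) |
| Pipeline & config | `R/pipeline.R`, `inst/cli/dentateqsm` |
| Compiled kernels | `src/unwrap.cpp`, `src/tfce.cpp`, `src/hull.cpp`, `src/medfilt.cpp` |

The methods vignette (`vignettes/dentate-qsm-methods.Rmd`) documents the
models, the synthetic-data design, every tunable parameter with its default
and rationale, and known limitations.
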