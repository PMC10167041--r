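# valve3d

Quantitative 3D morphometry of calcified aortic valve cusps from ex vivo
microfocus computed tomography (microCT).

Calcific aortic stenosis is the most common heart valve disease in
developed countries: mineral particles grow inside the valve cusps, the
cusps thicken, and the valve stops opening fully. Ex vivo microCT of
explanted cusps resolves this microstructure at the tens-of-micrometre
scale. `valve3d` is for researchers who have such scans (stacks of
reconstructed 2D slices) and want reproducible, per-cusp structural
metrics instead of one-off manual tool chains.

## What it computes

Given a reconstructed slice stack and its voxel size, the pipeline
produces:

* **Gray normalization** — 16-bit → 8-bit conversion over the dataset's
  dynamic range, then affine alignment of all datasets onto a reference
  scan via two in-scan reference materials (borosilicate bead, sample
  holder).
* **Cusp segmentation** — threshold 25–255 inside a region of interest,
  slice-wise 5×5 closing; cusp volume in mm³.
* **Calcification and density classes** — calcification at gray 75–255;
  low/moderate/high density classes (75/139/197 bounds, selectable by
  pooled 3-level Otsu, `multilevel_otsu()` + `pooled_thresholds()`) with a
  partial-volume-effect correction: HD is dilated by 2 voxels and removed
  before MD/LD are segmented, MD/LD are opened (2×2), and every class is
  dilated by 1 voxel to compensate the losses, with priority HD > MD > LD.
* **Particle morphometry** — 3D connected components (26-connectivity by
  default), particles of ≤ 10 voxels discarded, and a three-tier size
  classification: microscale ≤ 10⁻³ mm³, mesoscale in between, macroscale
  ≥ 1 mm³; particle counts per class, largest-particle volume and share,
  particles per mm³ of cusp.
* **Local thickness** — the largest-inscribed-sphere thickness map of the
  whole cusp (distance transform + sphere propagation, exact against a
  brute-force oracle), its volume-weighted mean, full histogram, and the
  volume fraction thinner than 0.7 mm (the healthy-cusp mean).
* **Group statistics** — exact Mann–Whitney tests (full enumeration for
  n ≤ 20), Pearson/Spearman correlations, valve-level pooling, and
  machine-readable JSON reports.

Because clinical scans cannot be redistributed, the package includes a
first-class synthetic phantom module (`phantom_spec()`,
`generate_phantom()`, `sample_cohort()`): a curved soft-tissue slab with
calcified inclusions of known geometry and density, a reference bead and
holder, Gaussian point-spread blur and seeded noise — with exact
pre-degradation ground truth for validation.

## Worked example

Analyse a synthetic cusp with known ground truth:

```r
library(valve3d)

ph <- generate_phantom(phantom_spec(seed = 42))
result <- run_cusp_pipeline(
  ph$volume, pipeline_config(),
  roi_mask      = ph$truth$roi_mask,
  anchor_masks  = list(holder = ph$truth$holder_mask, bead = ph$truth$bead_mask),
  ref_anchors   = reference_anchors(holder_mean = 20, bead_mean = 240),
  sample_id     = "N1.1", group_tag = "NF-LG"
)
result
#> <cusp_result> N1.1 (group NF-LG)
#>   cusp volume          151.66 mm^3
#>   calcified fraction      2.4 %
#>   particles                 7 (micro 0 / meso 6 / macro 1)
#>   largest particle       1.28 mm^3 (35.7% of calcification)
#>   PVE volume loss       -8.32 %
#>   mean thickness        1.519 mm (1.7% below 0.7 mm)
```

Reading the numbers: the phantom's ground-truth calcified fraction is
2.24%, recovered here as 2.4% (+7% relative, within the blur-induced
surface uncertainty); all 7 inclusions are recovered in their correct
size classes (the single macroscale particle is the 1.15 mm³ dense core,
measured 1.28 mm³ after the 75–255 segmentation); the 1.6 mm slab
measures 1.52 mm mean thickness, with 1.7% of the cusp volume thinner
than the 0.7 mm healthy-valve threshold. A negative PVE "volume loss"
(a net gain) is expected for isolated single-density inclusions — see the
methods vignette for why the correction behaves differently on nested
real calcifications.

Comparing groups uses the exact Mann–Whitney test:

```r
mw <- mann_whitney(c(12.1, 9.8, 15.5), c(26.9, 31.2, 50.9))
#> U = 0, p = 0.1 (exact), ns
```

`write_cusp_report()` exports each report as JSON;
`aggregate_valve()` pools the up-to-three cusps of one valve.

## Layout

* `R/`, `src/` — implementation (R with a small Rcpp core).
* `tests/testthat/` — unit, property and acceptance tests with their
  oracles.
* `vignettes/valve3d-methods.Rmd` — the model, parameter and design
  documentation.
* `scripts/acceptance.R` — end-to-end reproduction script.
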