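---
title: "Quantifying aortic valve calcification in 3D: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aortic valve calcification in 3D: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valve3d)
```

## The problem

Calcific aortic stenosis progressively stiffens the valve cusps: calcified
particles grow inside the soft tissue, the cusps thicken, and the valve
loses its aperture. Ex vivo microCT of explanted cusps resolves this
process at the tens-of-micrometres scale, far below what echocardiography
or clinical CT can see. `valve3d` turns a reconstructed microCT slice
stack into a quantitative per-cusp report: how much of the cusp is
calcified, how the mineral is distributed over density classes, how many
calcified particles exist and how large they are, and how thick the cusp
is everywhere.

The package mirrors a published ex vivo protocol while making every step
reproducible and testable in code. Because clinical scan data cannot be
redistributed, the package ships a synthetic phantom generator with exact
ground truth; every numerical claim made below is recomputed by the test
suite or by `scripts/acceptance.R` at run time.

## Pipeline stages and their parameters

### Gray-value normalization

Reconstruction exports 16-bit XY slices. `convert_16_to_8()` maps the
dataset's dynamic range (strict min/max by default; percentile clipping is
available via `percentile_clip` but off, since the protocol normalizes to
the dataset's own range) linearly onto 0–255, rounding half away from
zero — the rounding rule used everywhere gray values are quantized.
Datasets are then aligned across scans by `normalize_to_reference()`: the
scanner field of view contains two reference materials, a borosilicate
bead (bright) and the sample holder (dark), and the unique affine map
carrying a dataset's (holder, bead) mean grays onto the reference scan's
defines the normalization. Re-measuring the anchors after normalization
reproduces the reference values to within one gray level; the map is
idempotent at that tolerance. Anchor regions are supplied as masks (drawn
manually on real scans; provided by the phantom's ground truth here) —
automatic bead detection is out of scope.

### Cusp segmentation

`segment_cusp()` binarizes the entire cusp (soft tissue plus mineral) at
gray ≥ 25, inside a region of interest that excludes the sample holder,
then closes small holes with a 5×5 square applied per XY slice. The
threshold range 25–255 is inclusive at both ends. The named kernel is a
2D "square", so the closing is slice-wise by default; a 3D cube variant is
available through `pipeline_config(closing_3d = TRUE)` since the original
tool's behaviour in 3D is not documented. Closing is computed on a padded
domain, so it is extensive (no border voxel is ever removed) and
idempotent. Cusp volume is voxel count × (voxel size)³.

### Density decomposition with partial-volume correction

Calcification occupies gray values 75–255 within the cusp, split into
low (75–138), moderate (139–196) and high (197–255) density classes. The
class bounds are the component-wise means of per-sample 3-threshold Otsu
runs (`multilevel_otsu()`, which maximizes between-class variance by
exhaustive search over all increasing threshold triples with
lexicographic tie-breaking, computed over cusp voxels only so that
background air cannot dominate the variance; `pooled_thresholds()` does
the averaging).

At material boundaries the point-spread function mixes gray values, so
edge voxels of a dense core read as a lower density class. The correction
protocol of `pve_decompose()` runs verbatim in this order: segment HD;
dilate it by 2 voxels and remove it from the cusp; segment MD and LD
successively on the reduced domain; open MD and LD with a 2×2 slice-wise
square; dilate each class by 1 voxel to compensate the accumulated
erosion; resolve overlaps with priority HD > MD > LD and clip everything
to the cusp. The reported `volume_loss_fraction` compares the sum of the
corrected classes with the direct 75–255 segmentation.

Two genuinely open design points are resolved as follows:

* **Dilation kernel.** "Dilate by k voxels" uses the Euclidean ball
  (radius k; for k = 1 the 6-neighbour cross) rather than the 3×3×3 cube,
  switchable via `dilation_kernel = "cube"`. The PVE erosion being
  compensated is isotropic and sub-voxel to one-voxel in scale; the cube
  kernel adds about 1.5 voxels of effective radius per step and inflates
  a compensated sphere's volume by 25% or more at realistic inclusion
  sizes, overshooting the loss it is meant to repair. The ball adds about
  0.7–0.95 voxels and keeps the correction commensurate.
* **Operating envelope.** The ±1-voxel granularity of the compensation
  means the correction is quantitatively valid for single-density
  inclusions larger than roughly 12 voxels in radius. Two known biases
  remain outside that envelope, and both are measurable with the phantom:
  (i) classes whose lower gray bound sits close to soft tissue (LD
  especially) erode far less than one voxel under blur, so the fixed
  1-voxel compensation inflates small LD objects; (ii) the blurred halo
  of a *moderate*-density object passes through the LD gray band and, if
  wider than the 2×2 opening can remove (blur σ ≳ 1 voxel), is
  misassigned to LD — the protocol shields only HD by dilate-and-remove.
  The recovery experiment (`recovery_phantom_spec()`) therefore validates
  the correction where it claims validity: well-separated single-density
  inclusions above the blur scale.

The paper-style three-level decomposition assumes soft tissue plus three
mineral strata; the reported volume loss is condition-dependent (nested
real calcifications lose volume at every internal interface; isolated
single-density phantom spheres can show a net gain), so it is reported,
not asserted.

### Particle morphometry

`label_particles()` finds connected components of the all-density
calcification mask; 26-connectivity (face, edge, corner) is the default,
6-connectivity is available, and the choice is recorded in the report.
Particles of 10 voxels or fewer are discarded (`filter_small()`).
`particle_metrics()` classifies each particle: **microscale** ≤ 10⁻³ mm³,
**macroscale** ≥ 1 mm³, **mesoscale** strictly between — micro closed
above and macro closed below, with a 10⁻⁹ relative guard so volumes that
equal a boundary up to the float error of the cubed voxel size land on
the closed side. At 14 µm voxels the class boundaries correspond to
364.43 and 364 431 voxels; both voxel equivalents are recorded in the
summary for audit. Particle density ("per volume unit") is normalized by
the entire-cusp volume, the only per-sample volume defined.

### Local thickness

Thickness at a voxel is the diameter of the largest sphere containing the
voxel that fits entirely inside the cusp (largest inscribed sphere, the
standard 3D thickness definition). The digital convention is normative
for this package and is shared by the implementation and its brute-force
test oracle: the sphere centred at voxel q has radius `EDT(q) − 1/2`
voxels (Euclidean distance to the nearest background voxel centre, minus
half a voxel; everything outside the scanned array is background), and it
covers voxel p iff `|p − q| ≤ EDT(q)`. Consequences worth knowing:

* an axial slab of n voxels measures exactly n for odd n and n − 1 for
  even n (no voxel centre sits on an even slab's mid-plane);
* digital balls of diameter 8–24 voxels measure their nominal diameter
  within 10% (worst at d = 8: −9.4%);
* structures touching the array border are thin there, matching the
  physical reality of a cropped scan; border wedges at array edges carry
  reduced thickness.

The implementation is a 3D squared Euclidean distance transform
(separable lower-envelope algorithm) followed by sphere propagation from
non-redundant centres (a centre is dropped only when its sphere is
contained in a neighbour's, which cannot change the result), painting
largest spheres first with first-writer-wins run filling.
`thickness_summary()` reports the volume-weighted mean, the thickness
histogram as volume proportions (0.1 mm bins by default; the original
figure's binning is not printed), and the volume fraction thinner than
0.7 mm — the mean thickness of a healthy, non-calcified cusp, used as the
"normal thickness" threshold.

### Statistics

`mann_whitney()` compares a structural parameter between two diagnosis
groups: for combined n ≤ 20 the two-sided p comes from full enumeration
of rank assignments (midranks under ties; `p = Pr(|U − μ| ≥ |u − μ|)`),
otherwise from the normal approximation with tie-corrected variance; the
method used is recorded. `correlate()` wraps Pearson/Spearman with the
method as an explicit argument — the choice depends on normality of the
data and is left to the analyst rather than automated. Significance stars
follow the convention `*` < 0.05 to `****` < 0.0001, always alongside the
numeric p. No multiple-testing correction is applied, matching the
protocol being reproduced; reports say so implicitly by carrying raw p
values only. Valve-level summaries pool numerators and denominators over
a valve's cusps, so the valve fraction always lies between its cusp
fractions.

## The synthetic phantom

`phantom_spec()` renders a cusp-like scene with exact pre-degradation
ground truth: a bent soft-tissue slab (a section of a cylindrical shell
of 12 mm radius — reproducing the curved, 1.6–2.2 mm thick embedding
geometry that the thickness and volume metrics need), spherical or
ellipsoidal calcified inclusions placed on the shell mid-surface in bent
coordinates, a holder slab at the bottom and a reference bead in a top
corner. Rendering draws each structure at its nominal gray (background 5,
holder 20, soft tissue 45, LD 95, MD 165, HD 220, bead 240 — chosen to
straddle the protocol thresholds 25/75/139/197), convolves with a
Gaussian PSF, adds seeded Gaussian noise and scales to 16 bit.

Scale choices: the default grid is 192×192×96 voxels at an artificial
50 µm voxel size, so a full analysis runs in seconds while all metrics
stay mm-scaled; nothing downstream depends on the scanner's 14 µm because
every metric is voxel-size-parametric. The PSF default is 0.5 voxels: the
instrument's physical point spread (~20–25 µm) is a property of the
optics, and mapped onto the 50 µm grid it is about half a voxel. Noise
defaults to 2 gray levels, reconstruction-domain additive Gaussian noise
being the proxy; Poisson projection noise, beam hardening and ring
artifacts are deliberately not simulated. At 50 µm the microscale class
(≤ 10⁻³ mm³ = 8 voxels) falls entirely under the 10-voxel particle
filter, so default phantoms contain no micro inclusions; the micro/meso
boundary is exercised in unit tests at 14 µm and 100 µm instead.

What passing phantom tests shows — and does not show — about real data:
the phantom validates the geometry-independent mechanics (thresholding,
morphology, labelling, thickness, statistics) and the recovery of known
inclusion properties under blur and noise. It does not emulate nested
density gradients inside one calcification, soft-tissue texture,
beam-hardening cupping, or anatomical cusp shape, so quantitative biases
measured on phantoms (e.g. the PVE volume loss) transfer to real scans
only qualitatively.

`sample_cohort()` draws reproducible two-group cohorts with the milder
group A thinner (1.6 vs 2.2 mm mean base thickness), carrying fewer
mesoscale inclusions (5–9 vs 14–20) and smaller macroscale inclusions,
while both groups carry two macroscale inclusions — mirroring the
clinical observation that the largest particles are present in both
severity groups but differ in size while small particles differ in
number. Mesoscale inclusions fill a jittered 1 mm grid outside the macro
footprints, which guarantees non-overlap by construction; counts are
bounded by what fits without overlap on the 9.6 mm in-plane extent, so
the cohort contrasts are direction-faithful but scaled down from clinical
magnitudes.

## Numerical choices and degenerate inputs

* Rounding of gray values: half away from zero, everywhere.
* Thresholds and class bands: inclusive lower bounds; ranges read as
  closed intervals.
* Otsu: exhaustive search, ties broken toward the lexicographically
  smallest threshold tuple; histograms with fewer occupied bins than
  classes are rejected.
* Constant 16-bit volumes cannot be range-normalized (degenerate-range
  error); equal anchor means cannot anchor a normalization
  (degenerate-anchor error); empty cusp masks make volume fractions
  undefined (error) while empty calcification masks simply give zero.
* Empty masks: thickness maps are all-zero; summaries on empty maps are
  errors.
* The 2×2 opening kernel is even: it is anchored at the top-left voxel of
  its footprint, and opening/closing are anchor-independent by
  construction (they are unions of kernel translates), so the asymmetry
  cannot shift results.
* Kernel size validation: the closing kernel must be odd (it is centred);
  the opening kernel only ≥ 1, because the protocol's own opening kernel
  is the even 2.

## Problem sizes used in validation

The test suite validates oracle equivalence on exhaustive scales chosen
for completeness per CPU-minute: 100 random histograms for Otsu against
brute-force triple enumeration; 100 random masks up to 40³ for labelling
against flood fill; 20 masks (noise, blobs, digital balls) for thickness
against brute-force sphere fitting, plus digital balls of diameter 8–24;
full 192×192×96 phantoms for end-to-end recovery; and a 10-per-group
cohort for the group-contrast direction checks. `scripts/acceptance.R`
reruns the full pipeline on one default phantom, one recovery phantom and
a 6-per-group cohort.

## Known limitations

* No Hounsfield or mineral-density calibration: gray values are
  normalized, not radiodensity in standardized units.
* The LD class inherits moderate-density halos when blur reaches ~1 voxel
  (see the PVE envelope discussion above); LD volumes on heavily blurred
  data should be read as upper bounds.
* The thickness convention measures even-height slabs one voxel low;
  at 14 µm this is 14 µm of bias, far below anatomical effect sizes.
* ROI definition (sample-holder removal) is supplied, not detected.
* The phantom's cohort contrasts are qualitative emulations; absolute
  calcification fractions at desk scale (about 5% and 11% group means)
  sit at or below the lower end of the clinical range.
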