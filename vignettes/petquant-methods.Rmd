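---
title: "Quantitative PET/CT SUV analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative PET/CT SUV analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petquant)
```

## What the package computes

`petquant` is a quantitative analysis toolchain for whole-body
[18F]-FDG PET/CT in the setting where organ contours drawn on CT (by a
physician or a segmentation network) are transferred onto the PET grid
and summarized as standardized uptake values. The pipeline is:

1. read a PET series and its acquisition metadata (DICOM or NIfTI),
2. convert stored voxel values to body-weight SUV with decay correction,
3. resample CT-defined organ masks onto the PET grid (optionally after
   rigid mutual-information alignment),
4. report SUVmax and SUVmean per organ, both over the whole contour and
   over a fixed 1.2 cm-radius spherical VOI at the organ centroid,
5. delineate lesions at 40% / 50% of SUVmax, with total lesion
   glycolysis (TLG) and cumulative SUV histograms (CSH).

A synthetic dual-grid phantom generator and a desk-scale Swin-UNETR-style
segmentation backend make every stage testable end to end without any
clinical data.

## The SUV model

Body-weight SUV is computed voxel-wise as

$$\mathrm{SUV}_{bw} = \frac{(\mathrm{stored\ value} \cdot s + b)\,\cdot\, W\,[\mathrm{g}]}
  {D\,[\mathrm{Bq}] \cdot 2^{-\Delta t / T_{1/2}}}$$

where $s, b$ are the DICOM rescale slope/intercept mapping stored values
to activity concentration in Bq/mL, $W$ the patient weight, $D$ the
injected dose, $T_{1/2}$ the radionuclide half-life (F-18: 6586.2 s,
the packaged default when a series carries no half-life tag), and
$\Delta t$ = series time − radiopharmaceutical start time. With
concentration in Bq/mL and weight in grams the quantity is the
conventional dimensionless (g/mL) SUV; a healthy liver lands near
SUVmean ≈ 2, which pins the unit convention. Two details are deliberate:

* **Time source.** The formula names the *series* time. Acquisition
  time is often a few seconds to minutes later; `read_pet_series()`
  exposes `time_source = "acquisition"` as a switch, with "series" the
  default. If the scan clock has wrapped past midnight relative to the
  injection clock, 24 h are added (uptake intervals are about an hour;
  a negative interval is always a clock wrap).
* **Negative values.** Values that are negative after rescaling are
  passed through unchanged. Clipping is a display concern; statistics
  should see the data.

`decay_factor(dt, T)` is exactly $2^{-dt/T}$: 1 at $dt = 0$, 0.5 at one
half-life.

## The phantom generator: what it emulates and what it does not

`generate_phantom()` produces a CT volume, a raw PET volume, exact
masks on both grids, and the ground-truth SUV per organ.
The dual-grid geometry mirrors clinical whole-body acquisitions — CT
finer in-plane than PET (the `"study"` scale of
`example_phantom_spec()` uses the full 512×512 / 200×200 in-plane
matrices at 3 mm slices; the `"desk"` scale keeps the same structure in
a small field of view so that tests run in seconds).

The central design decision: **raw PET values are synthesized by
inverting the SUV formula** (stored value = SUV·dose·decay/(slope·weight)),
so that converting the noise-free phantom must return each organ's
target SUV exactly. The oracle (the inversion) is a three-line formula
independent of the image-processing path it tests.

Choices a user should know:

* Organs are axis-aligned ellipsoids; a voxel belongs to an organ iff
  its **center** is inside (no partial volume), so masks are exactly
  reproducible and mask volumes converge to $\tfrac43\pi abc$ only as
  spacing shrinks (within 2% at 1 mm isotropic).
* Default uptake values are typical FDG numbers chosen once: liver 2.0,
  spleen 1.6, bone marrow 1.2, breast background 0.8, tumor 8.
  Metadata defaults are a 70 kg patient and 370 MBq dose with 60 min
  uptake.
* Noise is additive Gaussian on raw stored values, clipped at zero.
  This supports the property tests; it is **not** PET physics — no
  Poisson counting statistics, scatter, attenuation or reconstruction
  artifacts. Passing phantom tests therefore validates arithmetic and
  geometry, not robustness to real scanner noise.
* A tumor may overlap its host organ (it overrides the host's uptake);
  any other organ overlap is an error naming both labels.

## Mask transfer, registration, dice

Masks are interchange objects (label volumes), not contour vertex
lists; transfer to another grid is nearest-neighbor resampling of the
mask itself. Images use trilinear interpolation; voxels mapping outside
the source extent read 0.

Rigid registration maximizes a 32-bin joint-histogram mutual
information, evaluated over the full fixed grid — no stochastic
sampling, so results are reproducible to the bit. The optimizer is a
regular-step pattern search over scaled parameters (one unit = 5 rad of
rotation, 1000 mm of translation): steps start at a radius of 0.009 and
halve whenever no axis move improves the metric, stopping below an
epsilon of 1.5e-4 or after 1000 sweeps. These scalars mirror the
optimizer settings quoted for the commercial alignment workflow this
package parallels; the mapping of those scalars onto a pattern search
is this package's own approximation and is not claimed identical to the
commercial implementation. On phantoms, translations up to 10 mm are
recovered within half a PET voxel.

`dice(a, b)` is $2|A\cap B|/(|A|+|B|)$, defined as 1 when both masks
are empty.

## Organ statistics: whole contour vs single VOI

`roi_statistics()` reports SUVmax (ties broken at the lowest linear
voxel index, location reported) and the arithmetic SUVmean.
`organ_suv_report()` adds the single-VOI route: a 1.2 cm-radius sphere
placed at the organ **centroid** (unweighted mean of member-voxel
centers). For concave organs the centroid can fall outside the organ;
the sphere is still placed there — deliberately, because the
literal centroid rule is reproducible, and the contour-vs-VOI
discrepancy it produces is precisely the effect the method comparison
quantifies. Spheres also use center-in-sphere membership, so the
12 mm VOI volume is within 3% of 7.238 mL on a 1 mm grid.

## Lesion delineation, TLG, CSH

`delineate_by_fraction()` thresholds at `fraction × SUVmax` **inclusive**
(≥), so the maximum voxel always belongs to the lesion and the result
at fraction → 1 is never empty. All supra-threshold voxels inside the
organ mask form the lesion by default; `largest_component = TRUE`
switches to the largest 6-connected component for focal analyses.

TLG is the per-voxel sum of SUV × voxel volume, identically equal to
SUVmean × volume (both routes are computed and tested against each
other). Units are SUV·mL with volumes in mL; printed clinical TLG
values are often unitless and may count voxels instead, so absolute
comparisons across software require knowing that convention.

The cumulative SUV histogram reports, for each threshold, the fraction
of region volume with SUV at or above it; thresholds span 0–100% of the
region's SUVmax (default grid: 101 points) or absolute SUV. The curve
is non-increasing and starts at 1. Hot lesions retain volume up to high
percent thresholds (convex downward); low-uptake tissue sheds volume
earlier relative to its own noise-dominated maximum (convex upward) —
the shape difference the package's tests reproduce on phantoms.

## Method agreement tables

`abs_diff_summary()` reproduces the "average difference" summaries of
paired measurement tables: mean of per-patient absolute differences
and their **population** (divisor *n*) standard deviation. The
population convention was pinned by re-deriving the printed ± values
from the packaged per-patient tables — sample sd (divisor *n−1*) does
not reproduce them. `grand_mean_of_organ_means()` aggregates per-organ
means unweighted and reports their range. One packaged summary cell
(the SUVmax liver ±) is not arithmetically consistent with its own
per-patient values under either convention; the package reports the
recomputed value.

## The segmentation backend

`build_model()` instantiates a Swin-UNETR-style network natively in R
(no deep-learning framework is required): a 2×2×2 patch embedding;
pairs of transformer blocks using window-based multi-head
self-attention, the second of each pair with shifted windows; patch
merging that halves token resolution and doubles channels, repeated
`n_stages` times; a residual 3×3×3 convolutional decoder with instance
normalization and skip connections; and a 1×1×1 softmax head over six
classes (background, right/left breast, liver, spleen, bone marrow —
the breasts are separate labels because laterality matters clinically).
Training uses dice + cross-entropy loss (1:1 by default) and Adam, with
flips/rotations (p = 0.1), intensity shifts (p = 0.5, offset 0.1) and
random 96³ crops at the `"study"` preset; CT preprocessing clips HU to
[−175, 250], scales to [0, 1] and resamples to 1.5×1.5×2.0 mm.

Deviations and choices made where the recipe is open:

* **Absolute position embedding** (`pos_embed = TRUE`): a learned
  per-token embedding is added after patch embedding. A pure
  relative-window design cannot distinguish left from right breast on
  small phantoms whose two breasts are intensity-identical; the
  embedding provides laterality directly. Relative position bias inside
  windows is omitted (windows are small at desk scale).
* **Window size** defaults to 7 at study scale (the conventional Swin
  choice, unstated in the recipe this mirrors) and is capped per stage
  to a divisor of the token grid.
* **Attention heads**: channels per head default to `embed_dim/3`
  (16 at embed 48, mirroring the 3-head convention).
* Learning rate (3e-3), MLP ratio (2 at desk scale) and the dice/CE
  weights are desk-scale defaults chosen for stable small-model
  training; none is attributed to the clinical recipe.
* Mixed-precision scaling is not implemented; all arithmetic is double
  precision, which favors determinism.

### Problem sizes

The `"desk"` preset trains an embed-12, 2-stage model on 24³ crops for
300 iterations — about 2.7×10⁵ parameters, minutes of CPU time. This is the
configuration the package's tests exercise: three phantom volumes are
overfitted to mean foreground dice ≥ 0.95, and the loss curve must fall.
That validates the architecture, the hand-written gradients and the
training loop. It says nothing about clinical segmentation accuracy:
the study-scale recipe (embed 48, 4 stages, 96³ crops, 20,000
iterations, 60 patients) requires GPU-class compute and real data, and
its reported accuracy is therefore explicitly out of scope here.

## Numerical details worth knowing

* Patient space is LPS mm throughout; voxel indices are 0-based in the
  coordinate maps. NIfTI affines (RAS) are converted on the way in/out.
* DICOM support is a minimal explicit-VR-little-endian codec (one frame
  per file, the radiopharmaceutical information sequence, 16-bit
  unsigned pixel data). It reads what it writes and errors loudly on
  anything else; clinical archives with compressed or enhanced
  multi-frame objects are out of scope.
* SUVmax ties: lowest linear index wins, recorded in the result.
* Resampling fill value is 0; degenerate (non-overlapping) grids give
  all-zero output rather than an error.
* The registration metric needs non-constant volumes; pure-noise pairs
  either fail to converge or stay near the identity with low
  similarity, and the convergence flag reports which happened.
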