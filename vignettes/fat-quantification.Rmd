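---
title: "Quantifying visible fat in sliced salami images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying visible fat in sliced salami images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatmorph)
```

## The measurement problem

Dry-cured salami carries its fat as discrete whitish particles in a red
meat matrix. When a salami is sliced, those particles appear as bright
spots against the matrix, and the fraction of the slice cross-section
they occupy — the *visible fat content* — is a fast, non-destructive
proxy for the product's fat level that also carries spatial information
(particle sizes, shapes, counts) that gravimetric chemical extraction
cannot provide. The working assumption is that a slice is representative
of the whole cylinder, reducing a 3-D composition problem to 2-D image
analysis.

`fatmorph` measures, per slice image:

* the slice area $A_s$ (cm²),
* per particle $i$: area $AF_i$, perimeter $P_i$, and roundness
  $$RF_i = \frac{P_i^2}{4\pi\,AF_i},$$
  the reciprocal of circularity — exactly 1 for a perfect circle,
  growing with elongation (a $2{:}1$ ellipse gives $\approx 1.19$, a
  square $4/\pi \approx 1.27$),
* the visible fat content
  $$\mathrm{VFC}\,(\%) = \frac{\sum_i AF_i}{A_s}\times 100,$$
* a ten-class particle-area frequency distribution,
* and per-sample means ± SD over replicate images, with a statistical
  layer (Duncan letters, correlation-matrix PCA, linear correlation
  against chemical fat).

## The segmentation chain

Images are slices photographed on a black light box, so three intensity
populations coexist: near-black backdrop, red matrix, whitish fat. The
chain is deterministic — the same image and configuration always produce
bit-identical results.

1. **Grayscale.** Standard luma weighting
   $0.299R + 0.587G + 0.114B$, rounded to 0–255.
2. **Contrast stretch.** A linear map sending the gray level at the
   lower percentile to 0 and at the upper percentile to 255 (default
   (1, 99)), clipping outside. A degenerate (constant) histogram is
   passed through unchanged with a notice.
3. **Median filter.** One pass with a square window (default 3×3)
   removes salt/pepper sensor noise without displacing particle
   boundaries. The filter is an exact integer median, computed as a
   vectorized binary search over the 0–255 intensity range; edges use
   replicate padding.
4. **Slice extraction.** The backdrop/slice threshold is the *lower cut
   of a three-class* between-class-variance (Otsu) criterion. A plain
   two-class Otsu is unreliable here: with realistic fat coverage
   (~12%) the dominant variance split lies between matrix and fat, not
   between backdrop and slice, and the "slice" collapses onto the fat
   blobs. The three-class lower cut separates the backdrop from
   everything else regardless of the fat share; when fewer than three
   populated classes exist it falls back to the two-class threshold.
   The largest 8-connected component is kept and its holes filled.
5. **Fat segmentation.** Otsu's two-class criterion *restricted to
   slice-interior pixels* (so the backdrop cannot bias the split),
   or a fixed gray level. The binary fat mask is closed with a square
   structuring element of side $2r+1$ (default $r = 1$) — closing the
   matrix outlines without materially changing particle area — then
   optionally hole-filled, intersected with the slice mask, labeled
   with 8-connectivity, and filtered by a minimum pixel area
   (default 4 px, well below any physically meaningful particle).

### Perimeter estimation

Digital perimeters are biased by construction: counting boundary-pixel
steps overestimates a disk's perimeter by up to ~27% (and would inflate
roundness by ~60%), while the common 4-direction Crofton estimator is
nearly exact on disks but ~5% low on axis-aligned squares. `fatmorph`
uses an 8-direction line-intercept (Cauchy–Crofton) estimator:
foreground/background transition counts along the axis, diagonal and
knight-move line families, each weighted by the family's perpendicular
line spacing ($1$, $1/\sqrt2$, $1/\sqrt5$). Verified accuracies:
digitized disks of radius 10/30/100 px give roundness errors of
1.8%/0.5%/0.05% (converging monotonically to 1), a 100×100 square gives
1.263 vs the exact $4/\pi = 1.273$, and 2:1 and 3:1 ellipses are within
1% of their continuous values. Note that digitized disks can land
marginally *below* 1; the continuous lower bound holds only up to
digitization error.

### Degenerate inputs and tie-breaks

* Otsu plateaus are broken at the plateau midpoint (the usual
  convention); a constant input yields *no* bright class (a fat-free
  noiseless slice measures 0 particles rather than an all-fat slice).
* Histogram binning is half-open and lower-inclusive; a particle area
  exactly on a class edge goes to the upper class. The last class is
  unbounded above.
* Particles touching the slice boundary are kept but flagged
  (`touches_border`).
* An image without calibration (`cm_per_pixel = NA`) is processed in
  pixel units with a warning on every cm²-labelled output.
* A single replicate summarises with SD 0 by convention, flagged by
  `replicates == 1`.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `contrast_percentiles` | (1, 99) | % | robust stretch; tolerates outlier pixels |
| `filter_window` | 3 | px | removes salt/pepper, preserves boundaries |
| `threshold_mode` | automatic | — | between-class variance inside the slice |
| `closing_radius` | 1 | px | square element of side 3; closes matrix outlines |
| `min_particle_area_px` | 4 | px | suppresses single-pixel noise |
| `area_class_edges` | 0, 0.1, 0.5, 1, 1.5, 2, 2.5, 3, 4, 5 | cm² | anchors: <0.1 intrinsic pork fat, 0.1–0.5 added lard, ≥5 largest class |
| `fill_holes` | TRUE | — | fat particles are solid tissue |

The area-class anchors reflect the two physical fat populations in this
product: sub-0.1 cm² intramuscular fat of the lean pork, and 0.1–0.5 cm²
pieces of lard added as an ingredient and deformed during mixing and
stuffing.

## The phantom generator

Because no public image set accompanies this protocol, validation rests
on synthetic phantoms with exact ground truth. `generate_phantom()`
renders a slice disk in a meat tone (150, 40, 45) on a near-black
backdrop (10, 10, 10) and places elliptical fat particles
(230, 225, 220): lognormal areas with median 0.1 cm² and `sdlog` 0.8
(giving mean areas around 0.07–0.14 cm² and maxima up to ~1.6 cm²),
aspect ratios uniform in [1, 3], uniform orientations. Placement is
rejection sampling with exclusion zones (each accepted footprint padded
by `min_separation`, default 6 px) and a bounded attempt budget, so
particles never overlap and stay clear of each other by more than the
closing window. Gaussian pixel noise (default SD 5 gray levels) and a
faint lateral illumination ramp (default ±2.5%) perturb the render. The
ground truth records the *exact rasterized pixel area* of every particle
and of the slice, so true VFC is known to the pixel, and the continuous
roundness of each generating ellipse is recorded via Ramanujan's
perimeter approximation.

`generate_study()` emulates a full acquisition: 16 samples (A–P) × 15
replicate images = 240 images, one PNG per replicate plus a master
ground-truth CSV. Default per-sample conditions span the realistic range
of this product class: target coverage rising 9%–18.5% and median
particle area 0.08–0.14 cm² across samples; each replicate jitters its
sample's coverage by a lognormal factor (sdlog 0.08), which reproduces
within-sample VFC spreads of about one percentage point. A single master
seed derives every per-image seed by fixed arithmetic, so any subset is
independently reproducible. Default frames are 512×512 px with a
200 px slice radius at 0.02 cm/px (a 4 cm slice radius).

**What the phantoms do not emulate** — and hence what passing tests do
*not* establish about real photographs: meat-matrix texture (real matrix
is not a uniform tone), casing and cut-edge artifacts, specular
highlights, color variation with ripening, and partially occluded or
out-of-focus particles. Phantom results validate the measurement
machinery, not the field performance of any particular camera setup.

## The statistical layer

**Duncan's multiple range test.** After a one-way ANOVA, the critical
range for a span of $r$ ordered means uses the studentized-range
quantile at Duncan's protected level $1-(1-\alpha)^{r-1}$ on the pooled
within-group mean square, with the harmonic mean of group sizes. Letters
are assigned by sweeping the sorted means: each letter covers a maximal
contiguous run whose range test is non-significant, which enforces
coherence (if two means share a letter, so does everything between
them). Zero within-group variance degenerates to exact comparison of
means. Note Duncan's test does *not* control the familywise error at
$\alpha$: under a complete null with $k$ groups the probability of any
separation is its protected level $1-(1-\alpha)^{k-1}$ (≈ 0.54 for
$k = 16$, $\alpha = 0.05$), and the package's Monte-Carlo validation
asserts exactly that value.

**PCA.** Variables are standardized and the correlation matrix is
eigendecomposed, so each feature contributes unit variance regardless of
units. Explained percentages are $100\,\lambda_j/p$ and always sum to
100; component signs are fixed by making each component's
largest-magnitude loading positive. The feature table is arbitrary: the
per-sample summaries run with or without a chemical-fat column.

**Correlation.** Ordinary least squares of chemical on visible fat, with
$R^2 = 1 - SS_{res}/SS_{tot}$; samples missing chemical values are
dropped with a warning.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
brute-force 3×3 medians, flood-fill connected components, numeric
ellipse arc-length quadrature, hand-binned histograms, and the
generator's exact pixel counts. End-to-end, noise-free well-separated
phantoms must return the exact particle count and VFC within one
percentage point of truth; at noise SD 8 the VFC tolerance is two
points. Monte-Carlo checks use 1000 null replicates for the Duncan
layer and 500 draws of 16 samples for the $R^2$ recovery around a
population value of 0.75. Reduced problem sizes (192–256 px phantoms,
2–3 replicates) are used where a test exercises plumbing rather than
accuracy; accuracy checks run at the full 512 px default geometry.

## Known limitations

* The (1, 99) percentile stretch assumes fat occupies a non-negligible
  share of the frame; below roughly 1% fat the stretch can saturate fat
  to the matrix level. Realistic products in this class carry 9–18%
  visible fat. For unusual samples, widen the percentiles or use a
  fixed threshold.
* Thresholding is intensity-only by design; no color-space or textural
  classification is attempted.
* Particle statistics are 2-D: no stereological correction to particle
  volumes is attempted.
* The calibration is a single isotropic cm/px scale; lens distortion
  and perspective are assumed negligible at a fixed camera geometry.
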