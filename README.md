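# fatmorph

Quantifies **visible fat** in digital photographs of sliced dry-cured
salami. Sliced fermented sausages carry their fat as bright, roughly
convex particles embedded in a red meat matrix; the share of the slice
cross-section they occupy, and their size and shape distributions, drive
both consumer perception and product characterisation. `fatmorph`
implements the classical image-analysis protocol for this measurement —
non-destructive, requiring only a camera and a black light box — together
with the statistical layer used to compare products, and a synthetic
phantom generator that makes every stage verifiable against exact ground
truth.

## What it computes

For each slice image (bright slice on a near-black backdrop):

1. 256-level grayscale conversion (luma weights 0.299/0.587/0.114),
   percentile contrast stretch, median filtering;
2. slice extraction (automatic between-class-variance threshold, largest
   connected component, hole filling) giving the slice area *A*ₛ;
3. fat segmentation inside the slice (Otsu threshold on slice-interior
   pixels, morphological closing with a square structuring element,
   8-connected labeling, minimum-size filtering);
4. per-particle morphometry: area *AF*ᵢ, line-intercept (Crofton)
   perimeter *P*ᵢ, and roundness

   *RF*ᵢ = *P*ᵢ² / (4·π·*AF*ᵢ)

   which equals 1 for a perfect circle and grows with elongation;
5. per-image summaries: particle count *n*, count per unit area *n*/*A*ₛ,
   mean/max area and roundness, a ten-class particle-area frequency
   distribution, and the visible fat content

   V FC (%) = Σᵢ *AF*ᵢ / *A*ₛ × 100;
6. per-sample aggregation over replicate images (mean ± SD), one-way
   ANOVA with **Duncan's multiple range** compact letter display, PCA on
   the **correlation matrix** of the per-sample features, and the linear
   correlation of visible against chemically measured fat.

## Worked example

```r
library(fatmorph)

# a synthetic slice with exactly known ground truth: 12% target coverage
ph <- generate_phantom(phantom_spec(coverage = 0.12, seed = 7))
attr(ph$truth, "true_vfc")
#> [1] 12.03  (exact pixel ratio of the rendered phantom)

m <- measure_slice(ph$image)
m
#> slice_measurement 'phantom_7': n = 33, A_s = 50.270, VFC = 12.01%

head(round(m$particles[, c("area_cm2", "perimeter_cm", "roundness")], 3), 4)
#>   area_cm2 perimeter_cm roundness
#> 1    0.174        1.656     1.257
#> 2    0.186        1.807     1.397
#> 3    0.368        2.224     1.069
#> 4    0.276        2.052     1.214

m$histogram$counts
#> [1] 12 18  3  0  0  0  0  0  0  0   # ten area classes, last unbounded
```

The measured visible fat content (12.01%) recovers the generator's exact
truth (12.03%) to within 0.02 percentage points, and all 33 particles are
found. Areas are in cm² via the 0.02 cm/px calibration; the roundness
column is dimensionless and ≥ 1 up to digitization error.

Correlating per-sample visible fat with chemical (Soxhlet) fat:

```r
correlate_vfc_chemical(c(8, 10, 12, 14, 16, 18),
                       c(11, 12.5, 15, 16, 19, 21.5))
#> chemical = 2.276 + 1.043 * visible   (R2 = 0.984, n = 6)
```

A full study emulation — 16 samples × 15 replicate images — and its
summary tables, Duncan letters, PCA figures and correlation plot are one
command away:

```sh
Rscript inst/cli/fatmorph.R all --out run_dir --seed 1
```

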