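Package: fatmorph
Title: Visible Fat Quantification in Sliced Cured-Meat Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image-analysis pipeline for quantifying visible fat in digital
    photographs of sliced dry-cured salami. Segments bright fat particles
    from the red meat matrix (grayscale conversion, percentile contrast
    stretch, median filtering, automatic thresholding, morphological closing
    with a square structuring element), measures per-particle morphology
    (area, line-intercept perimeter, roundness P^2/(4*pi*A)), computes
    visible fat content and ten-class particle-size distributions,
    aggregates replicate images into per-sample summaries, and provides the
    accompanying statistical layer: one-way ANOVA with Duncan's multiple
    range letters, principal component analysis on the correlation matrix,
    and linear correlation of visible versus chemically measured fat. A
    synthetic phantom generator with exact ground truth supports validation
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    grid,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
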