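---
title: "growthmap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{growthmap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthmap)
```

# The problem

Invasive lung adenocarcinoma usually grows as a mixture of architectural
patterns — acinar (gland-forming), micropapillary (small tufts without
fibrovascular cores), solid (sheets without glands) and cribriform
(sieve-like perforated nests) — and pathology reporting quantifies the
percentage of each pattern on the slide in 5% increments, because the
predominant pattern carries prognostic weight. growthmap implements a
whole-slide analysis pipeline for this task: it locates tissue, partitions
it into square tiles, classifies each tile into one of the four growth
patterns or non-tumor (NT) with a pluggable classifier applied contextually
over overlapping glimpses, assembles a per-tile tumor map, quantifies
pattern percentages, and scores the map against pathologist annotations
with confusion-matrix statistics.

The five classes are ordered AC < MP < SO < CR < NT throughout; integer
code 0 marks background/unclassified.

# Pipeline stages and their parameters

## Tissue masking

A ~5x rendering of the slide is converted to gray with BT.601 luma weights
and thresholded: pixels with luma < *t* = 230 are tissue foreground against
the white optical background. The mask is refined by filling enclosed
background holes and a binary morphological closing (5 × 5 square element).
Tiles whose footprint carries less than 20% mask foreground are deleted; a
tile at exactly 20% is kept. The closing element size, luma weights and
hole-filling step are exposed in the configuration because reasonable
refinements differ between scanners; the threshold and retention fraction
are the pipeline's operating points and rarely need changing.

## Tile grid and cross-scanner area matching

Tiles are axis-aligned squares placed at multiples of the tile edge from
the slide origin (0-based, half-open intervals); partial edge tiles are
dropped because the classifier input size is fixed. The reference tile is
600 px at 0.5 µm/px (a 300 µm physical edge at a typical 20x scan); for a
slide scanned at pixel size *s*, the edge is `round(600 * 0.5 / s)` px so
the physical tile area is preserved across scanners. The tile edge in
pixels, not the nominal area figure, is the operative definition.

## Color handling

Color transfer uses Reinhard's method in the decorrelated log-chromatic
lαβ space: RGB → LMS cone responses → log10 → a fixed decorrelating
rotation. Transfer matches per-channel mean and standard deviation to a
target pattern and converts back to RGB with clipping to [0, 255]. Two
numerical choices matter:

* **Matrix inversion.** The inverse LMS → RGB matrix is computed as the
  exact inverse of the forward matrix. Using the independently rounded
  published inverse leaves round-trip errors of almost two intensity
  levels on bright pixels, which would violate the identity-transfer
  contract (`target == source` must reproduce the tile within ±1 level).
* **Degenerate variance.** A zero source standard deviation (constant
  tile) is guarded with ε = 10⁻⁶, so constant tiles map onto the target
  means.
* **Gamut clipping and idempotence.** Normalizing a tile to a target is
  idempotent within ±1 level *provided the transfer stays inside the
  8-bit gamut*. When a tile with a very narrow intensity spread (e.g. a
  pure solid sheet) is matched to a wide pooled target, the variance is
  amplified many-fold, a quarter of the pixels can clip, and no clipping
  implementation can be idempotent. The augmentation-direction transfers
  (tiles onto k-means-derived cluster patterns) operate comfortably inside
  the gamut, and that is where the tests pin the property down.

Target color patterns are derived by k-means over tile-corpus pixels in
lαβ: each corpus is subsampled (50,000 pixels by default, seeded),
clustered separately, and `k_total` is split evenly across corpora — the
default four patterns from two corpora (two labs' staining habits) come
from 2 + 2 clusters. Initialization is deterministic farthest-point
seeding followed by Lloyd iterations (300 cap), so a fixed seed gives
bit-identical patterns. We read the corpus ambiguity in favour of *four
patterns in total* rather than four per cohort; the configuration accepts
any `k_total`. The inference-time normalization target defaults to the
pooled training-corpus statistics, selectable per config.

## Augmentation

Each labeled training tile is expanded by the product of color and
orientation alteration: the original plus one Reinhard transfer per target
pattern, each in the eight square symmetries (rotations by 0/90/180/270°
of the original, then of its diagonal flip). With four patterns this is
exactly (1 + 4) × 8 = 40 variants per tile; the reference corpus of
19,942 tiles expands to 797,680. Augmentation never resizes: downsizing
to the classifier input (256 px) happens at classification time so
archives stay resolution-faithful. A dry-run mode expands only the
manifest, so corpus bookkeeping does not require 800k files.

## Classifier contract

A classifier is anything with a `predict(tiles)` returning one length-5
probability vector per tile (entries ≥ 0, summing to 1 within 10⁻⁶) plus a
`normalize_input` flag stating whether the pipeline should Reinhard-
normalize glimpses before calling it. Two backends ship:

* `mock_model()` — a deterministic texture-rule classifier over
  interpretable features (dark-foreground fraction, connected components,
  enclosed lumina and their sizes). It exists to make the entire pipeline
  testable without training; its rules are keyed to the synthetic texture
  families below. It declares `normalize_input = FALSE`: its thresholds
  are defined on the generator's raw color scale, and stain normalization
  (which rescales per-tile contrast toward the target) would erase the
  pale-vs-dark distinction that separates non-tumor from tumor textures.
* `train_tiny_net()` — a seeded single-hidden-layer softmax network over
  area-downsampled tiles (12 × 12 × 3 by default). It is deliberately
  small: the point is to exercise the pluggable contract with a *learned*
  model reproducibly on a single CPU, not to reproduce large-CNN
  training, which is out of scope. It declares `normalize_input = TRUE`.

Batch standardization (zero mean / unit variance per channel over the
batch) is provided as the input-normalization contract for trainable
backends.

## Contextual soft voting

Every retained tile is classified together with up to eight overlapping
glimpses obtained by shifting the tile by `round(tile_px / 3)` pixels
horizontally, vertically and diagonally. Each glimpse is classified
independently and the tile receives the class maximizing the weighted sum
of per-glimpse class probabilities (uniform weights, N = 9 by default).
Decisions taken where the formulation is silent:

* **Borders.** Glimpses extending beyond the slide are dropped and N
  shrinks (the central glimpse always remains); padding would fabricate
  tissue, and clamping would double-count it.
* **Ties.** Broken deterministically toward the lowest class index
  (AC < MP < SO < CR < NT), for reproducibility.

With uniform weights the vote is permutation invariant, verified by test.
Under independent per-glimpse label noise (ε = 0.2, winner probability
0.6), majority-like voting over nine glimpses suppresses the error rate
roughly from 20% to the tail probability of five or more of nine
corruptions — the tests measure a ~20 percentage-point accuracy gain over
central-tile-only classification on homogeneous regions.

## Quantification and evaluation

The tumor map is the per-tile label grid; percentages are reported both
relative to all tissue tiles and relative to tumor tiles only, optionally
rounded to 5% increments with a largest-remainder correction so rounded
values still sum to exactly 100. Maps are rendered as alpha-blended color
overlays (fixed documented palette) at low magnification.

Evaluation superimposes the map onto the rasterized pathologist polygons
(even-odd fill rule, pixel-center inclusion) and counts pixels at the
ground-truth raster's resolution into a 5 × 5 confusion matrix (rows =
truth, columns = predicted). Annotated pixels over tiles that the tissue
filter discarded are tallied in a separate "unclassified" vector rather
than being folded into NT, which would bias the NT column. Slide matrices
aggregate by entrywise summation to set and study level; per-class F1 and
accuracy come from the standard closed forms, and a merged 2 × 2
tumor-vs-non-tumor summary treats within-tumor confusion as correct.
Overlapping annotation polygons of different classes are an error by
default (silent precedence would hide annotation bugs); a `last-wins`
override exists.

Nonparametric comparisons (rank-sum and signed-rank) are thin wrappers
over `stats::wilcox.test`: exact enumeration for small untied samples
(combined n ≤ 12), normal approximation with tie correction otherwise.
Zero paired differences are dropped; all-zero differences yield p = 1
with a warning. No multiple-comparison correction is applied; raw
p-values are reported.

# The synthetic-data generator

Real annotated whole slides cannot ship with a package, so every stage is
exercised on seeded synthetic slides. The generator emulates the
*statistical* structure the pipeline relies on, not histologic realism:

* dark-stained tumor elements on a bright (~247) background, pale pink
  non-tumor elements, per-element color jitter and pixel noise;
* two pseudo-cohort base palettes (a lighter and a darker purple, subtly
  different backgrounds) standing in for inter-laboratory H&E variance,
  so color-pattern derivation and Reinhard normalization have real work
  to do;
* five feature-separable texture families: NT — sparse pale elongated
  wisps; SO — densely packed discs merging into solid sheets; AC —
  annular elements with one small lumen each; MP — small tight elements
  in clear space; CR — large blobs perforated by six large lumina.

Class separability is a designed contract: the families differ in
dark-foreground fraction, component size and enclosed-lumen size, so the
texture-rule backend recovers the generating class with ≥ 95% per-tile
accuracy (measured at 100% in the tests at default parameters). AC and CR
are separated by *median lumen area* rather than lumina-per-component
because tile borders cut elements: a cut ring loses its lumen entirely
(it stops being enclosed), so hole sizes are crop-robust while
per-component counts are not. Textures are calibrated for tile edges of
96 px and above; pipeline tests use 96–128 px tiles.

Synthetic slides place one rectangular region per class on a slot grid
with one-tile gaps, aligned to the tile grid; the matching annotation
polygons are exactly the region rectangles, and the annotation XML
round-trips through the same reader used for real ImageScope exports.
The slide's pixel size is derived from the layout's tile edge
(600 × 0.5 / tile_px µm) so the pipeline's own physical-area matching
reproduces the layout's tile size — the desk-scale slide behaves as a
legitimately lower-resolution scan, not a special case.

What passing these tests shows — and does not show. They verify the
pipeline's mechanics end to end: masking keeps annotated tissue, tiling
and glimpse extraction are geometrically correct, voting and evaluation
match independent oracles, and a classifier satisfying the contract
propagates to near-perfect study-level scores. They do not show that any
particular classifier recognizes real H&E growth patterns; real tissue
has within-class morphological variance, stain gradients, artifacts and
ambiguous regions that the generator deliberately omits.

# Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data:
ten 11 × 7-tile slides (128 px tiles) for study-level recovery, twenty
paired replicates for the soft-voting comparison, 10⁴ random probability
sets for the voting oracle and 50 random map/mask pairs for the
evaluation oracle. These sizes give stable statistics on one CPU in a few
minutes. All randomness flows through explicit seeds (`withr::with_seed`);
configuration loading refuses to run stochastic paths without a seed, and
generation is bit-reproducible for a fixed seed.

# Known limitations

* The classifier backends are stand-ins; reproducing the reference
  large-CNN training (and hence cohort-level F1/accuracy values on real
  slides) is explicitly out of scope.
* Reinhard normalization is not idempotent under heavy gamut clipping
  (see above); stain-deconvolution methods are not implemented.
* No pen-mark/coverslip artifact removal, no blur QC, no adaptive
  thresholding; masks assume a bright optical background.
* Tumor outlines are tile-resolution rectangles, not vectorized
  polygons; map resolution equals the tile edge.

# A worked example

```{r example, eval = FALSE}
gen <- generate_slide(random_slide_layout(seed = 7), seed = 7, id = "demo")
res <- process_slide(gen$slide, mock_model(), gen$annotations)
res$metrics$acc              # five-class pixel accuracy vs the annotations
class_percentages(res$map, round_to_5 = TRUE)$tumor_pct
```
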