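---
title: "Quantifying cellular lipid storage from SRS images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cellular lipid storage from SRS images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SRSquant)
```

## The measurement problem

Lysosomal storage disorders of the Niemann–Pick family accumulate
unesterified cholesterol (type C) or sphingomyelin (type A) in late
endosomes and lysosomes. Stimulated Raman scattering (SRS) microscopy at
the 2845 cm⁻¹ CH₂ symmetric stretch gives a label-free, lipid-selective
greyscale channel in which stored lipid appears as bright punctate
droplets against the dimmer cell cytoplasm, with cell-free media darker
still. Quantifying storage from such images by hand invites selection
bias: which fields get measured, and where the thresholds sit, is up to
the operator. This package automates both decisions.

The readout is, per accepted field of view (FOV), the ratio of
lipid-droplet area to total intracellular area, optionally divided by the
number of cells, and per image the mean of that ratio over accepted FOVs.
Group comparisons (e.g. diseased vs control fibroblasts, vehicle vs
treated) are then ordinary univariate tests on per-image values.

## The two-layer pipeline

`runSrsPipeline()` composes five stages, all deterministic:

1. **Background bootstrap** (`estimateBackground()`). The image model is
   tri-modal — media, cytoplasm, droplets — so a two-threshold Otsu
   partition of the whole image is computed and its darkest class taken as
   the provisional media set. The background level is the mean (or median)
   of that set, and the cell/media threshold is
   `background + foregroundK · SD(media set)`, `foregroundK = 3` by
   default. A single-cut Otsu was rejected during development: on highly
   confluent, droplet-rich images its cut separates droplets from
   everything else, swallowing the media into the "background" class. In
   the exactly noiseless limit the media SD is zero and the lower Otsu
   cut, which lies strictly between the media and cytoplasm modes, is
   used instead. Pixels strictly above the threshold are foreground.
2. **Tiling** (`tileFovs()`). A `windowPx` × `windowPx` sliding window
   (default 250 px) at `stepPx` steps (default 100 px), keeping only
   windows fully inside the image; with the defaults a 2000 × 2000 image
   yields 18 × 18 = 324 overlapping FOVs. Overlap means pixels are
   deliberately counted in several FOVs; aggregates are over FOVs, not
   pixels.
3. **Confluence gate** (`computeConfluence()`, `selectFovs()`). A FOV's
   confluence is the fraction of its pixels classified foreground; FOVs
   with confluence ≥ `confluenceMin` (default 0.90, applied inclusively so
   the printed default passes) are included.
4. **Droplet segmentation** (`segmentLipidDroplets()`). Within each
   included FOV, intracellular pixels are split again: by default an Otsu
   cut restricted to intracellular intensities
   (`otsu_within_cells`), alternatively `mean + dropletK · SD`
   (`foreground_mean_plus_kSD`, `dropletK = 2`). Connected droplet
   components below `minDropletPx` (default 4 px) are discarded to
   suppress single-pixel noise. With zero intracellular contrast
   (constant intensities) no droplets are returned. Note the default rule
   assumes droplets are actually present in the cell population; on a
   droplet-free but noisy image an Otsu split of unimodal noise can call
   spurious droplet pixels, which the size filter largely, but not
   entirely, removes — the `foreground_mean_plus_kSD` rule is the
   conservative choice for near-zero storage.
5. **Cell counting** (`countCells()`). Default `component_count`: cells
   are size-filtered (≥ `minCellPx`, default 64 px) connected components
   of the foreground mask, and a FOV's count is the number of components
   intersecting it. Touching cells merge into one component — a known,
   tested bias of this mode. A marker channel (e.g. nuclei) or a
   user-provided table can replace it. Because it is not stated whether
   the original analysis normalized per FOV or per image, both are
   implemented (`normalizeBy = "fov"` divides each FOV's ratio by the
   cells intersecting that FOV; `"image"` divides by the whole-image
   count); per-FOV is the default.

Undefined quantities (a FOV with no intracellular pixels, a zero cell
count) are never NaN: they are `NA` plus an explicit flag column
(`ratio_defined`, `norm_defined`), and they propagate to CSV as empty
cells.

## The synthetic world

`generateSrsImage()` emulates the *statistical* structure of the lipid
channel, not Raman physics: a uniform background at `intensityBackground`
(default 10), cells as randomly placed ellipses with lognormal radius
dispersion, random orientation and smooth low-order Fourier boundary
perturbation at `intensityCell` (default 100), droplets as small discs
clipped to cell interiors at `intensityDroplet` (default 200), then
additive Gaussian noise (`noiseSd`, default 5) truncated at zero, or
Poisson noise. The default contrast and noise (cell/background ≈ 10:1,
droplet/cell 2:1, SD 5% of the cell level) were chosen once as
representative of a good-SNR SRS acquisition and are not tuned per test.
The default 2000 × 2000 px at 1 µm/px stands in for a 2 mm × 2 mm field
whose pixel dimensions the original acquisition does not state.

Cell number can be given directly (`nCells`) or derived from a target
`confluence` by inverting the Boolean coverage model
$c = 1 - \exp(-n A_{cell} / A_{img})$; coverage above 0.995 is refused
because random placement cannot reach full confluence (tests that need
"fully confluent" images use 0.97 against the 0.90 gate, or constant
images). Overlapping cells merge in the mask but every placed centre
counts toward `trueCellCount` — so the `component_count` bias is visible
against truth, by design. Droplet load is set either as
`dropletDensity` (droplets per cell) or as `targetLipidFraction`, which
places droplets in chunks until the mask-derived fraction reaches the
target (realized truth overshoots by at most a fraction of a percent and
is always recorded exactly). The returned `GroundTruth` stores the exact
masks and the exact droplet/cell pixel ratio; its validity method enforces
droplet ⊆ cell and exact agreement of the stored fraction with the masks.

What a green recovery test establishes: on tri-modal images with this
noise structure, the pipeline's mean FOV lipid ratio tracks the
mask-derived truth to within ±0.02 absolute and is unbiased within 20%
relative across seeds. What it does not establish: robustness to shading
gradients, out-of-focus light, spectral bleed-through, or confluence
textures unlike merged ellipses — real acquisitions should still be
spot-checked with the QC overlay (`writeOverlayPng()`).

The assay generators are exact by construction: expected media counts are
`fraction × countScale` (Poisson or Gaussian noise around them), and
expected target-gene Ct is shifted by −log₂(fold) relative to the
calibrator while the reference gene stays flat, so the downstream
formulas recover the configured truths exactly in the noiseless limit.

## Assay arithmetic

* `percentEfflux()` — 100 · media / (media + cells); complementary under
  swapping media and cells; zero-total wells are NA + warning.
* `subtractVehicle()` — subtracts the vehicle-group mean so vehicle
  centres exactly at zero; negative adjusted values are kept (clipping
  would bias group means) and flagged. Whether the original subtraction
  was per experiment or pooled is unstated; this implementation subtracts
  within the table it is given, which reduces to either convention
  depending on how tables are split.
* `percentViability()` — 100 · treated / mean(untreated).
* `ddctRelativeExpression()` — per sample ΔCt = Ct(target) −
  Ct(reference); per condition ΔΔCt against the calibrator; fold =
  2^−ΔΔCt. Technical replicates are averaged at the Ct level before
  differencing (the usual plate-software convention; a ΔCt-level mode is
  exposed). Invariant to plate-wide Ct offsets and to the reference
  gene's absolute level; no amplification-efficiency correction is
  attempted (out of scope).

## Statistics

`removeOneOutlierPerGroup()` implements the one-outlier-per-group rule as
a two-sided Grubbs test at α = 0.05 — the documented outlier method of
the graphing software named in the original workflow; the exact variant
and α used there are not stated, so these defaults are declared rather
than inferred. At most one point per group is ever removed, removals are
always returned, and groups under n = 3 pass through untouched with a
warning. Note the masking caveat inherent to Grubbs: two comparable gross
outliers inflate the SD and can shield each other.

`compareGroups()` covers the three designs used on these readouts:
pooled-variance unpaired two-tailed t test (Welch selectable), one-way
ANOVA with Tukey HSD, and two-way ANOVA with Bonferroni-adjusted pairwise
comparisons of the first factor within each level of the second. The
two-way design uses Type II sums of squares (each main effect adjusted
for the other, interaction last), computed by nested-model comparison;
on balanced data this equals the sequential decomposition, which is the
tested cross-check. Degenerate inputs (zero variance everywhere) raise an
explicit error rather than returning NaN statistics.

The test suite calibrates the machinery: one-way ANOVA type-I error is
0.05 ± 0.02 over 1000 null simulations, the Grubbs null removal rate at
n = 10 stays ≤ 10%, and the chained rule (screen, then test) is verified
to keep empirical α below 0.10 at nominal 0.05 — slightly anticonservative,
as expected when outlier screening precedes testing, and documented here
rather than hidden.

## Numerical and interface choices

* Coordinates are 0-based, row-major, half-open windows
  `[r, r+w) × [c, c+w)`; windows that would overhang are dropped, never
  padded.
* Threshold tie-breaks: strictly-greater-than for foreground
  classification; ≥ for the confluence gate and the tile gate.
* Otsu thresholds return the upper edge of the argmax histogram bin (256
  bins single-cut, 128 per axis for the two-cut variant); constant input
  returns the constant, so "no contrast" cleanly yields zero foreground
  or zero droplets.
* Connected components use compiled two-pass union-find labelling,
  8-connectivity, labels compacted in scan order.
* All generators draw from a locally seeded Mersenne-Twister stream and
  restore the caller's RNG state, so identical parameters + seed are
  bit-identical and no global state leaks.
* TIFF I/O is a deliberately minimal baseline codec (single channel,
  uncompressed, 8/16-bit unsigned or 32-bit float): integer data
  round-trip exactly, multi-channel or multi-page files are rejected with
  errors naming the problem, and pixel size travels in the resolution
  tags. It interoperates with standard TIFF readers; compressed or tiled
  TIFFs are out of scope.

## Worked example

```{r example, eval = FALSE}
g <- generateSrsImage(imageGenParams(
  heightPx = 1000, widthPx = 1000, confluence = 0.95,
  targetLipidFraction = 0.10, seed = 7))
s <- runSrsPipeline(g$image)
s
trueLipidFraction(g$truth)   # the mask-derived truth the estimate tracks
```

## Known limitations

* The droplet Otsu rule over-segments droplet-free noisy cells (see
  above); use `foreground_mean_plus_kSD` when storage near zero is
  expected.
* `component_count` undercounts touching cells; use a nuclear marker
  channel when accurate per-FOV counts matter.
* The generator's merged-ellipse confluence is smoother than real
  monolayer texture; gate behaviour near the 0.90 boundary on real data
  deserves visual QC.
* Physical-unit outputs assume square pixels and trust the stated or
  stored pixel size.
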