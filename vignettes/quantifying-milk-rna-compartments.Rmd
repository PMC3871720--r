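---
title: "Quantifying the cellular and exosomal RNA compartments of milk"
author: "lactoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the cellular and exosomal RNA compartments of milk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactoscan)
```

## The measurement problem

Milk carries RNA in two physically distinct compartments. Nucleated
somatic cells (immune and epithelial cells) contain both RNA and DNA.
Cytoplasmic crescents are slivers of mammary epithelial cytoplasm that
get trapped between the plasma-membrane layers enveloping a milk fat
globule as it is secreted; they contain RNA but no nucleus. Which
compartment dominates matters for anyone using milk as a non-invasive
window on mammary gene expression: crescent RNA reports on the secretory
epithelium, cellular RNA on whatever cells happen to be in the milk.

Acridine orange (AO) separates the two optically. Bound to RNA its
emission peaks near 650 nm (red); bound to DNA near 525 nm (green).
An AO-stained whole-milk spread imaged in three channels --
differential interference contrast (DIC) for the fat globules, one
fluorescence channel for AO-RNA, one for AO-DNA -- therefore shows
crescents as red (RNA-only) objects hugging globule boundaries, and
nucleated cells as yellow (RNA+DNA) objects. `lactoscan` turns such
stacks into two per-image numbers:

* **crescent incidence** -- the percentage of milk fat globules
  carrying at least one linked crescent;
* **cellular RNA percentage** -- the share of segmented RNA signal
  attributable to nucleated cells, the complement being exosomal
  (crescent) RNA.

## Pipeline

For each image (`analyzeStack()`):

1. **Globule detection** (DIC). Globules appear as bright-rimmed "gray
   bubbles", not filled disks, so the default `"gradient"` strategy
   thresholds the smoothed Sobel gradient magnitude, closes the rim mask
   (3x3), fills holes, and labels 8-connected components, followed by
   area (>= 50 px^2) and circularity (>= 0.6) filters. The
   `"intensity"` strategy thresholds the smoothed plane directly and
   suits simple or synthetic images whose rims carry real intensity
   contrast. Circularity is `4*pi*area/perimeter^2` with the perimeter
   estimated from the exposed-boundary-edge count with a pi/4 Crofton
   correction -- exact for digital disks and cheap enough for tens of
   thousands of objects; values are clamped at 1.05 against
   discretization.
2. **Fluorescence segmentation.** Each channel is Gaussian-smoothed
   (sigma 1 px), thresholded (Otsu per image or per tile, or fixed),
   labelled with 8-connectivity (thin crescent arcs fragment under
   4-connectivity), and filtered at 5 px^2. Integrated intensity is the
   background-subtracted sum over the component extended 2 px outward
   (nearest object wins), where background is the median below-threshold
   intensity, clamped at zero per pixel. The 2 px extension matters:
   smoothing pushes a perimeter-proportional share of a thin object's
   signal just outside the thresholded mask, and crescents have much
   higher perimeter/area ratios than cells, so without recapture the
   cellular/exosomal ratio is biased by several percentage points.
   Object areas and label maps always refer to the undilated component.
3. **Classification.** Each RNA object's fraction of member pixels
   inside the DNA mask (dilated 1 px to tolerate chromatic
   misregistration) is compared against `coloc_fraction` = 0.3,
   boundary inclusive: at or above is a nucleated cell, below is a
   crescent candidate. A fractional rule is used rather than
   pixel-perfect overlap because channel registration is never exact.
4. **Linking.** Every crescent links to the globule minimizing
   `||centroid difference|| - equivalent_radius`, i.e. distance to the
   idealized globule boundary; plain centroid distance would misassign
   small crescents sitting on large globules. Ties break to the lowest
   globule id; beyond `max_link_distance` (25 px) a crescent becomes an
   orphan. Orphans stay in the exosomal RNA pool -- crescents do detach
   during spreading, and dropping their signal would bias attribution --
   but contribute no globule to the incidence numerator.
5. **Summary.** A globule with several linked crescents counts once.
   With no globules the incidence is reported missing (`NA`), not zero.
   The RNA denominator is the sum over segmented objects only; diffuse
   sub-threshold skim signal is excluded, a deliberate and configurable
   reading of "percent of milk RNA".

### Automatic-threshold safety

Otsu always returns a cut. On a plane with no real signal (a DNA channel
of a field without cells, or an empty tile) the cut lands mid-noise and
a naive pipeline turns speckle into one giant "object" -- we observed
crescents being reclassified as cells this way. Automatic thresholds are
therefore accepted only if they clear the below-threshold median by
`min_contrast_sigma` (default 4) robust standard deviations; otherwise
the channel yields zero objects. Fixed thresholds bypass the guard,
which is also the documented operating mode for genuinely low-contrast
channels where Otsu's bimodality assumption fails (see below).

### Tiling

Whole-slide scans are processed in tiles (`tileIterator()`): cores
partition the image exactly (half-open intervals), tiles add `overlap`
margin on interior sides, and an object belongs to the tile whose core
contains its centroid. With `overlap` at least twice the largest object
diameter every object is seen whole by its owning tile, so tiled and
whole-image runs agree; crescent-globule linking is re-run globally on
the aggregated record tables, which is cheap and provably identical to
re-linking only near core boundaries. Thresholds are computed per tile
-- the right behaviour under illumination drift across a slide -- which
leaves counts and incidence bit-identical to a whole-image run while
intensity sums (hence the RNA percentages) agree only to the per-tile
threshold jitter, in practice well under 0.05 percentage points on
synthetic slides.

## The synthetic scene generator

Real stained micrographs with ground truth do not exist, so the package
ships a generator (`generateScene()`, `renderChannels()`) that emulates
the described appearance of AO-stained whole milk and knows the truth
exactly:

* **Globules**: non-overlapping disks, truncated-lognormal radii
  (median 8 px, sigma_log 0.25, truncated to [5, 20] px), placed by
  rejection sampling on a spatial hash with >= 6 px boundary clearance.
  The lower truncation reflects that sub-resolution globules are not
  countable objects; the upper bound caps object diameter for the
  tiling-overlap contract.
* **Crescents**: annular arcs hugging the outside of the owner's
  boundary (radial extent `[r, r + 3]` px, 35% of the circumference),
  matching the adherent morphology seen in micrographs and making
  boundary-distance linking geometrically correct. Incidence is either
  Bernoulli per globule or an exact count of distinct owners.
* **Cells**: free-floating disks (radius 5 px) carrying both RNA and
  DNA signal, placed in the space between globules.
* **Rendering**: DIC draws each globule as a 2 px bright rim on a
  mid-gray background; RNA draws crescents and cell cytoplasm; DNA
  draws cells only. Gaussian blur (sigma 1 px) then Gaussian noise
  (sigma 5 on a background of 50 and object levels of 400, i.e. high
  single-object SNR typical of stained spreads) are applied per
  channel. Signal units are arbitrary; only ratios are contractual, and
  before blur/noise the summed RNA plane above background equals the
  ground-truth signal sum exactly.

RNA objects keep a clearance of at least `3 * blur_sigma + 2` px from
one another (crescent orientations are re-drawn until free; in
exact-count mode a blocked owner is replaced from the unused globules,
preserving the configured count). This enforces the resolvability
premise under which detection can be exact; it does not make detection
trivial, since blur, noise and thresholding still intervene.

Generation is bit-reproducible from the seed and restores the caller's
RNG state. Packings whose effective area demand exceeds ~55% of the
canvas (the random-sequential-adsorption regime) fail fast with an
error, as do per-object placements after a bounded retry budget.

What the generator does **not** emulate: DIC optics (shear shadows,
interference fringes), overlapping or occluding globules, out-of-focus
planes, autofluorescence gradients, or the unknown real distribution of
crescent sizes ("various sizes" is all the literature offers -- the
defaults are declared, not fitted). Passing recovery tests on these
scenes therefore demonstrates correctness of the measurement logic
under the stated imaging model, not performance on any particular
microscope's output.

## Calibrated recovery experiments

The two headline statistics are validated by parameter recovery at the
published operating points (the test suite and `scripts/acceptance.R`
recompute all of these; no number below is asserted without being
computed):

* **Incidence**: slide-scale scenes of 20,000 globules on a 5000 x 5000
  px canvas (the canvas is sized for a realistic ~20% globule area
  fraction; much smaller canvases put the required packing near the
  jamming limit), with the crescent-bearing count fixed to `round(p*N)`
  at p = 5.34% and 7.34%. The pipeline recovers both to two decimals --
  every globule found, every crescent found, every link correct --
  in about 80 s per scene on one CPU.
* **Cellular share**: 512 x 512 scenes, 200 globules, 20 cells, with
  the ground-truth cellular share of integrated RNA calibrated to
  21.5%, 14.2% and 14.1%; recovery is within a few tenths of a
  percentage point (tolerance +/- 2). Calibration chooses the crescent
  count whose expected total arc area balances the cell area at the
  target share and then rescales the crescent RNA level for exactness
  (`calibrateSceneParams()`): per-pixel AO brightness is similar for
  crescent and cell cytoplasm in reality, so a realistic scene reaches
  a target share through areas, not through order-of-magnitude level
  differences -- which Otsu could not segment anyway.
* **The sub-1% regime** (0.8% cellular share) is exercised with two
  small cells against a heavy crescent load and fixed RNA/DNA
  thresholds (background + ~6 noise SD): a class 100x dimmer than the
  dominant one violates Otsu's bimodality assumption in principle, so
  pinned thresholds are the documented low-signal operating mode.
  Recovery is within +/- 0.5 points.

## Attribution modes and their bias

`cellular_rna_pct` defaults to integrated-intensity attribution because
RNA mass tracks fluorescence yield better than projected area. The
`"area"` mode is retained for comparability, with a caveat the tests
make explicit: under blur, thresholding costs a thin arc relatively
more suprathreshold area than a round cell, so area-mode shares carry a
shape-dependent bias (about 2 points at a 50% share under default
blur). On blur-free renders, where masks equal footprints, the two
modes agree to well under a point at equal per-pixel brightness.

## Numerical and degenerate-input choices

* Coordinates are 0-based; `x` is the column, `y` the row; centroids
  are arithmetic means of member-pixel coordinates. Areas are reported
  in px^2 and, when a pixel size is supplied, in um^2.
* Planes are used at native intensity scale; no normalization at load.
  Channel identity is always caller-declared (`channel_map`, 1-based
  plane indices) because TIFFs carry no reliable channel metadata.
* Smoothing and gradients use separable clamped-shift convolutions with
  replicate boundaries; their cost does not depend on how the image
  dimensions factorize (FFT convolution degenerates on prime-ish
  dimensions at slide scale).
* Zero-variance planes yield zero objects with a warning, never an
  error; a batch continues past individually failing images, recording
  the failure in the summary's `status` column.
* Linking ties break deterministically to the lowest globule id;
  equality of floating-point distances is honoured as stated rather
  than fuzzed.
* Exact quartile convention: linear interpolation between order
  statistics (`quantile(type = 7)`); box widths scale with sqrt(n),
  normalized to the largest group. Two-group tests default to Welch
  with Satterthwaite degrees of freedom (a pooled option exists); a
  degenerate comparison of two zero-variance equal-mean groups returns
  p = 1 by convention.

## Problem sizes in the shipped checks

The test suite and acceptance script use: two 5000^2 scenes with 20,000
globules (incidence recovery), 512^2 scenes with 200 globules for share
recovery and the 20-seed recovery sweep, an 1800^2 scene with 2,000
globules for whole-vs-tiled agreement, and 1,000 random instances of up
to 50 x 50 objects for the linking oracle. These sizes were chosen so
the whole battery reproduces the slide-scale behaviour of the method
while completing in a few minutes on a single CPU.

## Known limitations

* Touching globules are not split (no watershed in this version);
  merged components inflate areas and deflate counts. The per-image
  fraction of low-circularity objects
  (`attr(records, "low_circularity_fraction")`) serves as a merge
  alarm. On real DIC the `"gradient"` strategy's dilated edge responses
  merge objects closer than about 6 px; the circularity filter then
  drops such pairs.
* The colocalization rule, thresholds and link-distance cap are
  declared defaults, exposed in the configuration, not reconstructions
  of any reference implementation: the original method's values are not
  published.
* Absolute RNA yield (ng) is out of scope; only within-image ratios are
  measured. Between-sample statistics operate on the per-image summary
  table and assume images are comparable preparations.
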