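# lactoscan

Quantification of milk fat globules, cytoplasmic crescents and nucleated
cells in acridine-orange-stained whole-milk micrographs.

## The problem

Milk RNA comes from two compartments. **Cytoplasmic crescents** are
slivers of mammary epithelial cytoplasm trapped between the membrane
layers of a secreted milk fat globule: RNA-positive, anucleate, and a
non-invasive window on the secretory epithelium. **Nucleated cells**
(immune and epithelial cells in milk) carry both RNA and DNA. Anyone
profiling milk RNA needs to know which compartment their signal comes
from.

Acridine orange (AO) separates them optically: bound to RNA it emits
near 650 nm (red), bound to DNA near 525 nm (green), so crescents are
red-only objects adherent to globule boundaries and nucleated cells are
yellow. With a DIC channel locating the fat globules, a three-channel
stack supports two per-image statistics, which this package computes:

- **crescent incidence** — % of globules with at least one linked
  crescent:
  `100 · |{g : ∃ crescent linked to g}| / n_globules`;
- **cellular RNA share** — % of segmented RNA attributable to cells:
  `100 · Σ_cells I / (Σ_cells I + Σ_crescents I)`, with `I` the
  background-subtracted integrated AO-RNA intensity (or object area in
  `"area"` mode).

The pipeline: segment globules in DIC (gradient or intensity
thresholding, hole filling, area/circularity filters) → segment RNA and
DNA objects (Otsu or fixed thresholds, 8-connected components) →
classify each RNA object by its DNA-mask overlap fraction (≥ 0.3 ⇒
cell) → link each crescent to the globule minimizing
`‖Δcentroid‖₂ − equivalent_radius` (ties to the lowest id, distant
crescents kept as orphans) → summarize. Whole-slide scans are processed
by overlap tiling with exact core partitioning. A synthetic scene
generator with exact ground truth makes every stage testable without
micrographs, and a small statistics layer (Welch t-tests, boxplot
summaries, OLS fits) covers between-sample comparisons.

## Worked example

```r
library(lactoscan)

scene  <- generateScene(sceneParams(seed = 42))   # 512x512, 200 globules
stack  <- renderChannels(scene)                   # DIC + AO-RNA + AO-DNA
result <- analyzeStack(stack,
                       segmentationParams(globule_strategy = "intensity"))
milkSummary(result)
#> MilkSummary 'synthetic-seed42' (intensity attribution)
#>   globules: 200   crescents: 11 (11 linked, 0 orphan)   cells: 10
#>   globules with crescents: 5.50%
#>   RNA: 50.76% cellular / 49.24% exosomal
```

All 200 globules, 11 crescents and 10 cells are recovered; 11 of 200
globules carry a crescent (5.50%), and 50.76% of the segmented RNA
signal is cellular — against a ground-truth share of 50.58%
(`groundTruthCellularShare(scene)`). Per-object records carry
coordinates, areas and links:

```r
head(crescents(result), 3)
#>   crescent_id        x        y area_px2 linked_globule_id link_distance
#> 1           1 105.1957 455.8043      138                36     -1.985074
#> 2           2 138.8880 212.2720      125                49     -1.723054
#> 3           3 233.9135 406.2500      104                93     -1.225769
```

(Negative link distances mean the crescent centroid sits fractionally
inside the idealized globule disk, as expected for adherent arcs.)

Real images enter through `loadChannelStack(path, channel_map)` —
channel identity is always caller-declared — and batches through
`batchProcess()` / the CLI:

```sh
Rscript inst/cli/lactoscan.R quantify slides/*.tif --config run.yaml --out results/
Rscript inst/cli/lactoscan.R simulate --seed 7 --out sim/
Rscript inst/cli/lactoscan.R compare results/summary.csv --group species --out results/
```

## Documentation

The methods vignette
(`vignettes/quantifying-milk-rna-compartments.Rmd`) describes the
imaging model, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, numerical
choices, and known limitations.
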