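Package: lactoscan
Title: Quantification of Milk Fat Globules, Cytoplasmic Crescents and
    Somatic Cells in Acridine-Orange-Stained Milk Micrographs
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects milk fat globules in the differential interference
    contrast (DIC) channel and RNA/DNA-positive objects in the acridine
    orange (AO) fluorescence channels of three-channel whole-milk
    micrographs, classifies RNA objects as exosomal cytoplasmic crescents
    or nucleated somatic cells by RNA-DNA colocalization, links every
    crescent to its closest globule, and computes per-image summary
    statistics: the percentage of globules carrying at least one crescent
    and the percentage of milk RNA attributable to nucleated cells versus
    crescents. Large slide scans are processed by overlap tiling. A
    synthetic scene generator renders AO-stained milk fields with exact
    ground truth so the whole pipeline is testable without micrographs,
    and a small statistics layer provides the Welch t-tests, boxplot
    summaries and linear fits used to compare samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: CellBiology, Preprocessing, Segmentation, Visualization
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
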