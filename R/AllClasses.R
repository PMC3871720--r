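#' @import methods
NULL

setOldClass(c("SceneParams", "list"))
setOldClass(c("SegmentationParams", "list"))
setOldClass(c("LinkParams", "list"))
setOldClass(c("RunConfig", "list"))

#' Three-channel micrograph stack
#'
#' A `ChannelStack` holds the three registered 2-D intensity planes of one
#' acridine-orange-stained whole-milk field: the DIC plane (globules appear
#' as gray bubbles), the AO-RNA fluorescence plane (~650 nm emission) and
#' the AO-DNA fluorescence plane (~525 nm emission). Planes are stored as
#' numeric matrices indexed `[row = y + 1, col = x + 1]` with 0-based pixel
#' coordinates `x` (column) and `y` (row) used throughout the package.
#'
#' @slot dic numeric matrix, DIC intensity plane (arbitrary units).
#' @slot rna numeric matrix, AO-RNA intensity plane.
#' @slot dna numeric matrix, AO-DNA intensity plane.
#' @slot pixelSize physical edge length of one pixel in micrometres;
#'   `1.0` means areas are effectively reported in px^2.
#' @slot imageId source identifier string.
#' @slot bitDepth original bit depth of the source file (`NA_integer_` when
#'   the stack was built in memory).
#'
#' @seealso [loadChannelStack()], [renderChannels()], [analyzeStack()]
#' @export
setClass("ChannelStack",
  representation(
    dic = "matrix",
    rna = "matrix",
    dna = "matrix",
    pixelSize = "numeric",
    imageId = "character",
    bitDepth = "integer"
  ),
  prototype(pixelSize = 1, imageId = "", bitDepth = NA_integer_)
)

setValidity("ChannelStack", function(object) {
  msgs <- character()
  d <- dim(object@dic)
  if (!identical(d, dim(object@rna)) || !identical(d, dim(object@dna)))
    msgs <- c(msgs, "all three planes must share identical height and width")
  for (ch in c("dic", "rna", "dna")) {
    v <- slot(object, ch)
    if (!is.numeric(v))
      msgs <- c(msgs, sprintf("channel '%s' is not numeric", ch))
    else if (anyNA(v) || any(!is.finite(v)))
      msgs <- c(msgs, sprintf("channel '%s' contains non-finite values", ch))
    else if (any(v < 0))
      msgs <- c(msgs, sprintf("channel '%s' contains negative intensities", ch))
  }
  if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msgs <- c(msgs, "pixelSize must be a single positive number")
  if (length(object@imageId) != 1)
    msgs <- c(msgs, "imageId must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ChannelStack
#'
#' @param dic,rna,dna numeric matrices of identical dimensions.
#' @param pixelSize pixel edge length in micrometres (default 1).
#' @param imageId source identifier.
#' @param bitDepth original bit depth, if known.
#' @return A validated [ChannelStack-class] object.
#' @examples
#' z <- matrix(0, 16, 16)
#' ChannelStack(z, z, z, imageId = "empty")
#' @export
ChannelStack <- function(dic, rna, dna, pixelSize = 1, imageId = "",
                         bitDepth = NA_integer_) {
  new("ChannelStack",
      dic = as.matrix(dic) + 0, rna = as.matrix(rna) + 0,
      dna = as.matrix(dna) + 0,
      pixelSize = as.numeric(pixelSize), imageId = as.character(imageId),
      bitDepth = as.integer(bitDepth))
}

#' Tile of a larger micrograph
#'
#' A sub-stack cut from a parent image for memory-bounded processing. The
#' `coreBounds` rectangle (0-based, half-open, in parent coordinates
#' `c(x0, x1, y0, y1)`) marks the region whose detections are
#' authoritative; the margin outside it is overlap shared with neighbours.
#' The cores of all tiles of one image partition the parent exactly.
#'
#' @slot stack the cropped [ChannelStack-class].
#' @slot originX,originY 0-based pixel offset of the tile's top-left corner
#'   within the parent image.
#' @slot coreBounds integer vector `c(x0, x1, y0, y1)`, half-open, parent
#'   coordinates.
#' @seealso [tileIterator()]
#' @export
setClass("Tile",
  representation(
    stack = "ChannelStack",
    originX = "integer",
    originY = "integer",
    coreBounds = "integer"
  )
)

setValidity("Tile", function(object) {
  msgs <- character()
  cb <- object@coreBounds
  if (length(cb) != 4)
    return("coreBounds must be c(x0, x1, y0, y1)")
  d <- dim(object@stack@dic)
  tx0 <- object@originX; ty0 <- object@originY
  tx1 <- tx0 + d[2]; ty1 <- ty0 + d[1]
  if (cb[1] < tx0 || cb[2] > tx1 || cb[3] < ty0 || cb[4] > ty1)
    msgs <- c(msgs, "coreBounds must lie within the tile")
  if (cb[1] >= cb[2] || cb[3] >= cb[4])
    msgs <- c(msgs, "coreBounds must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic AO-milk scene with exact ground truth
#'
#' Holds the generator parameters and the true object lists of a simulated
#' whole-milk field: globules (center, radius), cytoplasmic crescents
#' (owner globule, arc geometry, total RNA signal) and nucleated cells
#' (center, radius, total RNA and DNA signal). The scene is purely
#' geometric; [renderChannels()] rasterizes it into a [ChannelStack-class]
#' deterministically.
#'
#' @slot params the effective generator parameters (see [sceneParams()]);
#'   includes any calibrated intensity level.
#' @slot globules data.frame: `gt_id, x, y, radius, has_crescent`.
#' @slot crescents data.frame: `gt_id, owner_id, theta, x, y, area_px2,
#'   rna_signal`.
#' @slot cells data.frame: `gt_id, x, y, radius, area_px2, rna_signal,
#'   dna_signal`.
#' @seealso [generateScene()], [groundTruth()]
#' @export
setClass("SyntheticScene",
  representation(
    params = "list",
    globules = "data.frame",
    crescents = "data.frame",
    cells = "data.frame"
  )
)

#' Detection result for one image
#'
#' All objects detected in one micrograph (or one tiled slide), the label
#' maps when retained, the parameters used, and the per-image
#' [MilkSummary-class].
#'
#' @slot imageId source identifier.
#' @slot globules data.frame: `globule_id, x, y, area_px2, equiv_radius,
#'   circularity`.
#' @slot crescents data.frame: `crescent_id, x, y, area_px2,
#'   integrated_intensity, dna_overlap_fraction, linked_globule_id,
#'   link_distance, orphan`.
#' @slot cells data.frame: `cell_id, x, y, rna_area_px2, dna_area_px2,
#'   integrated_rna_intensity, dna_overlap_fraction`.
#' @slot labels list of label matrices (`globules`, `rna`, `dna`); empty
#'   for tiled runs where label maps are not aggregated.
#' @slot params list of the segmentation/linking parameters and provenance
#'   (tiling grid, thresholds).
#' @slot summary the per-image [MilkSummary-class].
#' @export
setClass("SceneResult",
  representation(
    imageId = "character",
    globules = "data.frame",
    crescents = "data.frame",
    cells = "data.frame",
    labels = "list",
    params = "list",
    summary = "ANY"
  )
)

#' Per-image summary statistics
#'
#' The two headline measures for one milk image: the percentage of milk fat
#' globules carrying at least one linked cytoplasmic crescent, and the
#' percentage of segmented milk RNA attributable to nucleated cells (the
#' complement being exosomal, i.e. crescent, RNA). RNA attribution uses
#' background-subtracted integrated intensities by default; `"area"` mode
#' substitutes object areas.
#'
#' @slot imageId source identifier.
#' @slot nGlobules,nCrescents,nCrescentsLinked,nCrescentsOrphan,nCells
#'   object counts.
#' @slot pctGlobulesWithCrescents percentage of globules with >= 1 linked
#'   crescent; `NA` when no globules were detected (undefined, not 0).
#' @slot cellularRnaPct,exosomalRnaPct RNA attribution percentages; they
#'   sum to 100 whenever any RNA object exists, otherwise both are `NA`.
#' @slot attributionMode `"intensity"` or `"area"`.
#' @seealso [summarizeScene()]
#' @export
setClass("MilkSummary",
  representation(
    imageId = "character",
    nGlobules = "integer",
    nCrescents = "integer",
    nCrescentsLinked = "integer",
    nCrescentsOrphan = "integer",
    nCells = "integer",
    pctGlobulesWithCrescents = "numeric",
    cellularRnaPct = "numeric",
    exosomalRnaPct = "numeric",
    attributionMode = "character"
  )
)

setValidity("MilkSummary", function(object) {
  msgs <- character()
  cnt <- c(object@nGlobules, object@nCrescents, object@nCrescentsLinked,
           object@nCrescentsOrphan, object@nCells)
  if (any(cnt < 0)) msgs <- c(msgs, "counts must be >= 0")
  p <- object@pctGlobulesWithCrescents
  if (!is.na(p) && (p < 0 || p > 100))
    msgs <- c(msgs, "pctGlobulesWithCrescents must lie in [0, 100]")
  cp <- object@cellularRnaPct; ep <- object@exosomalRnaPct
  if (!is.na(cp) && !is.na(ep) && abs(cp + ep - 100) > 1e-9)
    msgs <- c(msgs, "cellularRnaPct + exosomalRnaPct must equal 100")
  if (!object@attributionMode %in% c("intensity", "area"))
    msgs <- c(msgs, "attributionMode must be 'intensity' or 'area'")
  if (length(msgs)) msgs else TRUE
})
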