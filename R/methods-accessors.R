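#' @rdname ChannelStack-class
setMethod("dicChannel", "ChannelStack", function(object) object@dic)

#' @rdname ChannelStack-class
setMethod("rnaChannel", "ChannelStack", function(object) object@rna)

#' @rdname ChannelStack-class
setMethod("dnaChannel", "ChannelStack", function(object) object@dna)

#' @rdname ChannelStack-class
setMethod("pixelSize", "ChannelStack", function(object) object@pixelSize)

#' @rdname ChannelStack-class
setMethod("imageId", "ChannelStack", function(object) object@imageId)

#' @rdname ChannelStack-class
#' @export
setMethod("dim", "ChannelStack", function(x) dim(x@dic))

#' @rdname ChannelStack-class
#' @export
setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@dic)
  cat(sprintf("ChannelStack '%s': %d x %d px (h x w), pixel size %g um%s\n",
              object@imageId, d[1], d[2], object@pixelSize,
              if (is.na(object@bitDepth)) ""
              else sprintf(", source %d-bit", object@bitDepth)))
  for (ch in c("dic", "rna", "dna")) {
    v <- slot(object, ch)
    cat(sprintf("  %s: range [%g, %g]\n", ch, min(v), max(v)))
  }
  invisible(NULL)
})

#' @rdname Tile-class
setMethod("coreBounds", "Tile", function(object) object@coreBounds)

#' @rdname Tile-class
setMethod("tileOrigin", "Tile", function(object)
  c(x = object@originX, y = object@originY))

#' @rdname Tile-class
#' @export
setMethod("show", "Tile", function(object) {
  d <- dim(object@stack@dic)
  cb <- object@coreBounds
  cat(sprintf(
    "Tile at (x=%d, y=%d), %d x %d px, core [%d,%d) x [%d,%d)\n",
    object@originX, object@originY, d[1], d[2], cb[1], cb[2], cb[3], cb[4]))
  invisible(NULL)
})

#' @rdname SyntheticScene-class
setMethod("groundTruth", "SyntheticScene", function(object)
  list(globules = object@globules, crescents = object@crescents,
       cells = object@cells))

#' @rdname SyntheticScene-class
setMethod("sceneParameters", "SyntheticScene", function(object) object@params)

#' @rdname SyntheticScene-class
#' @export
setMethod("show", "SyntheticScene", function(object) {
  p <- object@params
  cat(sprintf(
    "SyntheticScene %d x %d px (seed %d)\n", p$height, p$width, p$seed))
  cat(sprintf("  %d globules, %d crescents, %d cells\n",
              nrow(object@globules), nrow(object@crescents),
              nrow(object@cells)))
  if (nrow(object@crescents) || nrow(object@cells))
    cat(sprintf("  ground-truth cellular RNA share: %.2f%%\n",
                groundTruthCellularShare(object)))
  invisible(NULL)
})

#' @rdname SceneResult-class
setMethod("globules", "SceneResult", function(object) object@globules)

#' @rdname SceneResult-class
setMethod("crescents", "SceneResult", function(object) object@crescents)

#' @rdname SceneResult-class
setMethod("cells", "SceneResult", function(object) object@cells)

#' @rdname SceneResult-class
setMethod("milkSummary", "SceneResult", function(object) object@summary)

#' @rdname SceneResult-class
setMethod("imageId", "SceneResult", function(object) object@imageId)

#' @rdname SceneResult-class
#' @export
setMethod("show", "SceneResult", function(object) {
  cat(sprintf("SceneResult '%s'\n", object@imageId))
  cat(sprintf("  %d globules, %d crescents (%d orphan), %d cells\n",
              nrow(object@globules), nrow(object@crescents),
              sum(object@crescents$orphan), nrow(object@cells)))
  if (is(object@summary, "MilkSummary")) show(object@summary)
  invisible(NULL)
})

#' @rdname MilkSummary-class
#' @param object a `MilkSummary`.
#' @export
setMethod("show", "MilkSummary", function(object) {
  cat(sprintf("MilkSummary '%s' (%s attribution)\n",
              object@imageId, object@attributionMode))
  cat(sprintf("  globules: %d   crescents: %d (%d linked, %d orphan)   cells: %d\n",
              object@nGlobules, object@nCrescents, object@nCrescentsLinked,
              object@nCrescentsOrphan, object@nCells))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", v)
  cat(sprintf("  globules with crescents: %s\n",
              fmt(object@pctGlobulesWithCrescents)))
  cat(sprintf("  RNA: %s cellular / %s exosomal\n",
              fmt(object@cellularRnaPct), fmt(object@exosomalRnaPct)))
  invisible(NULL)
})

#' Flatten a MilkSummary to a one-row data.frame
#'
#' Column names match the batch summary CSV written by [batchProcess()].
#'
#' @param x a [MilkSummary-class].
#' @param row.names,optional,... ignored; present for S3 compatibility.
#' @return one-row `data.frame`.
#' @export
as.data.frame.MilkSummary <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(
    image_id = x@imageId,
    n_globules = x@nGlobules,
    n_crescents = x@nCrescents,
    n_crescents_linked = x@nCrescentsLinked,
    n_crescents_orphan = x@nCrescentsOrphan,
    n_cells = x@nCells,
    pct_globules_with_crescents = x@pctGlobulesWithCrescents,
    cellular_rna_pct = x@cellularRnaPct,
    exosomal_rna_pct = x@exosomalRnaPct,
    attribution_mode = x@attributionMode,
    stringsAsFactors = FALSE
  )
}

#' @export
setMethod("as.data.frame", "MilkSummary", as.data.frame.MilkSummary)
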