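#' @rdname ChannelStack-class
#' @param object,x a `ChannelStack`, `Tile`, `SyntheticScene`,
#'   `SceneResult` or `MilkSummary` as documented per method.
#' @export
setGeneric("dicChannel", function(object) standardGeneric("dicChannel"))

#' @rdname ChannelStack-class
#' @export
setGeneric("rnaChannel", function(object) standardGeneric("rnaChannel"))

#' @rdname ChannelStack-class
#' @export
setGeneric("dnaChannel", function(object) standardGeneric("dnaChannel"))

#' @rdname ChannelStack-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname ChannelStack-class
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))

#' @rdname SceneResult-class
#' @export
setGeneric("globules", function(object) standardGeneric("globules"))

#' @rdname SceneResult-class
#' @export
setGeneric("crescents", function(object) standardGeneric("crescents"))

#' @rdname SceneResult-class
#' @export
setGeneric("cells", function(object) standardGeneric("cells"))

#' @rdname SceneResult-class
#' @export
setGeneric("milkSummary", function(object) standardGeneric("milkSummary"))

#' @rdname SyntheticScene-class
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname SyntheticScene-class
#' @export
setGeneric("sceneParameters", function(object)
  standardGeneric("sceneParameters"))

#' @rdname Tile-class
#' @export
setGeneric("coreBounds", function(object) standardGeneric("coreBounds"))

#' @rdname Tile-class
#' @export
setGeneric("tileOrigin", function(object) standardGeneric("tileOrigin"))
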