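#' Summarize one image's detections
#'
#' Computes the two headline measures. The crescent-incidence percentage
#' counts globules with at least one linked crescent (a globule with
#' several linked crescents counts once) over all detected globules; it
#' is undefined (`NA`) when no globules were detected. The cellular RNA
#' percentage divides the cells' total by the total over cells plus all
#' crescents -- orphans included, since detached crescents are still
#' exosomal signal -- using background-subtracted integrated intensities
#' (`mode = "intensity"`, default) or object areas (`mode = "area"`).
#' Diffuse sub-threshold skim signal is never part of the denominator.
#'
#' @param globules,crescents,cells record data.frames for one image, as
#'   produced by the segmentation and linking stages.
#' @param mode `"intensity"` or `"area"`.
#' @param image_id identifier copied into the summary.
#' @return a [MilkSummary-class].
#' @examples
#' g <- data.frame(globule_id = 1:3)
#' x <- data.frame(crescent_id = 1:2, area_px2 = c(40, 50),
#'                 integrated_intensity = c(0, 0),
#'                 linked_globule_id = c(1L, 2L), orphan = FALSE)
#' summarizeScene(g, x, data.frame())  # 66.67% of globules with crescents
#' @export
summarizeScene <- function(globules, crescents, cells,
                           mode = c("intensity", "area"), image_id = "") {
  mode <- match.arg(mode)
  nG <- nrow(globules)
  nX <- nrow(crescents)
  orphan <- if (nX) crescents$orphan else logical(0)
  nLinked <- sum(!orphan)
  pct <- if (nG == 0) NA_real_ else {
    bearing <- length(unique(crescents$linked_globule_id[!orphan]))
    100 * bearing / nG
  }
  cellTot <- crescTot <- 0
  if (mode == "intensity") {
    if (nrow(cells)) cellTot <- sum(cells$integrated_rna_intensity)
    if (nX) crescTot <- sum(crescents$integrated_intensity)
  } else {
    if (nrow(cells)) cellTot <- sum(cells$rna_area_px2)
    if (nX) crescTot <- sum(crescents$area_px2)
  }
  if (cellTot + crescTot > 0) {
    cellular <- 100 * cellTot / (cellTot + crescTot)
    exosomal <- 100 - cellular
  } else {
    cellular <- exosomal <- NA_real_
  }
  new("MilkSummary",
      imageId = as.character(image_id),
      nGlobules = as.integer(nG),
      nCrescents = as.integer(nX),
      nCrescentsLinked = as.integer(nLinked),
      nCrescentsOrphan = as.integer(nX - nLinked),
      nCells = as.integer(nrow(cells)),
      pctGlobulesWithCrescents = pct,
      cellularRnaPct = cellular,
      exosomalRnaPct = exosomal,
      attributionMode = mode)
}

#' Run the full detection pipeline on one stack
#'
#' Segments globules (DIC), RNA and DNA objects (fluorescence channels),
#' classifies RNA objects by DNA colocalization, corrects globule
#' geometry, links crescents to globules and summarizes. With `tile_size`
#' set, the stack is processed tile by tile ([tileIterator()]) and the
#' per-tile detections merged by [aggregateTiles()]; thresholds are then
#' computed per tile, which tracks illumination drift across a slide.
#'
#' @param stack a [ChannelStack-class].
#' @param params a [segmentationParams()] bundle.
#' @param link a [linkParams()] bundle.
#' @param mode RNA attribution mode, `"intensity"` or `"area"`.
#' @param tile_size optional tile edge length in px; `NULL` processes the
#'   stack whole.
#' @param overlap tile overlap in px (see [tileIterator()]).
#' @param keep_labels retain label matrices in the result (whole-image
#'   runs only).
#' @return a [SceneResult-class] whose `summary` slot holds the
#'   [MilkSummary-class].
#' @export
analyzeStack <- function(stack, params = segmentationParams(),
                         link = linkParams(),
                         mode = c("intensity", "area"),
                         tile_size = NULL, overlap = 104L,
                         keep_labels = is.null(tile_size)) {
  mode <- match.arg(mode)
  stopifnot(is(stack, "ChannelStack"))
  if (!is.null(tile_size)) {
    tiles <- tileIterator(stack, tile_size, overlap)
    parts <- lapply(tiles, .analyzeTile, params = params)
    return(aggregateTiles(parts, link = link, mode = mode,
                          image_id = stack@imageId))
  }
  g <- segmentGlobules(stack@dic, params)
  r <- segmentChannelObjects(stack@rna, params$min_rna_area, params, "rna")
  d <- segmentChannelObjects(stack@dna, params$min_dna_area, params, "dna")
  cls <- classifyRnaObjects(r$labels, r$objects, d$labels > 0, params)
  # segmentGlobules fills holes before measuring, so the geometry
  # correction contract is already satisfied (it is idempotent)
  cres <- linkCrescents(cls$crescents, g$records, link)
  summ <- summarizeScene(g$records, cres, cls$cells, mode,
                         image_id = stack@imageId)
  new("SceneResult",
      imageId = stack@imageId,
      globules = g$records, crescents = cres, cells = cls$cells,
      labels = if (keep_labels)
        list(globules = g$labels, rna = r$labels, dna = d$labels)
      else list(),
      params = list(segmentation = params, linking = link,
                    attribution_mode = mode,
                    thresholds = c(dic = g$threshold, rna = r$threshold,
                                   dna = d$threshold)),
      summary = summ)
}

# Detect and classify within one tile; coordinates shifted to the parent
# frame. Linking is deferred to aggregation.
.analyzeTile <- function(tile, params) {
  st <- tile@stack
  g <- segmentGlobules(st@dic, params)
  r <- segmentChannelObjects(st@rna, params$min_rna_area, params, "rna")
  d <- segmentChannelObjects(st@dna, params$min_dna_area, params, "dna")
  cls <- classifyRnaObjects(r$labels, r$objects, d$labels > 0, params)
  shift <- function(df) {
    if (nrow(df)) {
      df$x <- df$x + tile@originX
      df$y <- df$y + tile@originY
    }
    df
  }
  list(image_id = st@imageId,
       core = tile@coreBounds,
       globules = shift(g$records),
       crescent_candidates = shift(cls$crescents),
       cells = shift(cls$cells))
}

#' Merge per-tile detections into one image result
#'
#' Keeps each object only in the tile whose core rectangle contains its
#' centroid (half-open intervals make the assignment unique), re-issues
#' globally consecutive ids, re-links every crescent against the full
#' globule table (linking on records is cheap, and a global pass is
#' provably identical to re-linking only near core boundaries), and
#' summarizes. With `overlap >= 2 x` the largest object diameter, each
#' object is seen whole by the tile that owns it, making tiled and
#' whole-image runs agree.
#'
#' @param tile_results list of per-tile detection lists (internal layout
#'   produced by [analyzeStack()] in tiled mode).
#' @param link a [linkParams()] bundle.
#' @param mode RNA attribution mode.
#' @param image_id identifier of the parent image.
#' @return a [SceneResult-class] (label maps are not aggregated).
#' @export
aggregateTiles <- function(tile_results, link = linkParams(),
                           mode = c("intensity", "area"), image_id = NULL) {
  mode <- match.arg(mode)
  if (!length(tile_results)) stop("no tile results to aggregate")
  ids <- unique(vapply(tile_results, `[[`, character(1), "image_id"))
  if (length(ids) != 1)
    stop("inconsistent tile provenance: tiles come from different images: ",
         paste(ids, collapse = ", "))
  if (is.null(image_id)) image_id <- ids
  inCore <- function(df, core) {
    if (!nrow(df)) return(df)
    keep <- df$x >= core[1] & df$x < core[2] &
            df$y >= core[3] & df$y < core[4]
    df[keep, , drop = FALSE]
  }
  glob <- do.call(rbind, lapply(tile_results, function(t)
    inCore(t$globules, t$core)))
  cresc <- do.call(rbind, lapply(tile_results, function(t)
    inCore(t$crescent_candidates, t$core)))
  cel <- do.call(rbind, lapply(tile_results, function(t)
    inCore(t$cells, t$core)))
  if (is.null(glob)) glob <- .emptyGlobuleRecords()
  if (is.null(cel)) cel <- data.frame()
  if (is.null(cresc)) cresc <- data.frame(x = numeric(0), y = numeric(0),
                                          area_px2 = numeric(0),
                                          integrated_intensity = numeric(0))
  rownames(glob) <- rownames(cresc) <- NULL
  if (nrow(glob)) glob$globule_id <- seq_len(nrow(glob))
  if (nrow(cel)) {
    rownames(cel) <- NULL
    cel$cell_id <- seq_len(nrow(cel))
  }
  linked <- linkCrescents(cresc, glob, link)
  summ <- summarizeScene(glob, linked, cel, mode, image_id = image_id)
  new("SceneResult",
      imageId = as.character(image_id),
      globules = glob, crescents = linked, cells = cel,
      labels = list(),
      params = list(linking = link, attribution_mode = mode,
                    n_tiles = length(tile_results)),
      summary = summ)
}

#' Batch-process a set of micrographs
#'
#' Runs [loadChannelStack()] + [analyzeStack()] over every path. A failure
#' on one image is caught, logged in the `status` column of the summary
#' table, and does not abort the batch.
#'
#' @param paths character vector of TIFF paths (must be non-empty).
#' @param config a [runConfig()] list (segmentation, linking, tiling,
#'   attribution and channel-map settings).
#' @return list with `summaries` (one row per image, canonical summary
#'   columns plus `status`) and `objects` (concatenated
#'   [objectTable()]s of the successful images).
#' @export
batchProcess <- function(paths, config = runConfig()) {
  if (!length(paths)) stop("empty path list")
  config <- .validateConfig(config)
  seg <- do.call(segmentationParams, config$segmentation)
  lnk <- do.call(linkParams, config$linking)
  rows <- vector("list", length(paths))
  objs <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    res <- tryCatch({
      stack <- loadChannelStack(paths[i], config$channel_map,
                                pixel_size = config$pixel_size)
      r <- analyzeStack(stack, seg, lnk, mode = config$attribution_mode,
                        tile_size = config$tiling$tile_size,
                        overlap = config$tiling$overlap,
                        keep_labels = FALSE)
      objs[[i]] <- objectTable(r, config$pixel_size)
      cbind(as.data.frame(milkSummary(r)), status = "ok",
            stringsAsFactors = FALSE)
    }, error = function(e) {
      empty <- as.data.frame(summarizeScene(
        .emptyGlobuleRecords(), data.frame(), data.frame(),
        mode = config$attribution_mode, image_id = basename(paths[i])))
      cbind(empty, status = paste0("failed: ", conditionMessage(e)),
            stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  list(summaries = do.call(rbind, c(rows, make.row.names = FALSE)),
       objects = if (length(objs <- Filter(Negate(is.null), objs)))
         do.call(rbind, c(objs, make.row.names = FALSE))
       else .emptyObjectTable())
}
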